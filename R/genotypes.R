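#' Sex-aware X-chromosomal genotype dataset
#'
#' Stores calls for unrelated individuals at the panel loci. Males are
#' hemizygous and carry exactly one allele per locus; females carry an
#' unordered pair. Missing calls are allowed and are excluded locus-wise
#' from all counting.
#'
#' @param panel an [xstr_panel()] (or `NULL` to build a bare panel from the
#'   column names, with unknown map positions).
#' @param sample_id character vector of unique sample identifiers.
#' @param sex character vector, `"M"` or `"F"`.
#' @param a1,a2 character matrices (samples x loci) of allele labels.
#'   For males `a2` must be `NA`; for females `a1`/`a2` are both set or both
#'   `NA`. Column names are locus names and must appear in the panel.
#' @return An object of class `xstr_dataset`.
#' @export
xstr_dataset <- function(panel, sample_id, sex, a1, a2) {
  sample_id <- as.character(sample_id)
  sex <- toupper(as.character(sex))
  if (anyDuplicated(sample_id)) stop("duplicate sample_id")
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  loci <- colnames(a1)
  if (is.null(loci) || !identical(loci, colnames(a2)))
    stop("a1 and a2 must share locus column names")
  if (is.null(panel)) {
    panel <- xstr_panel(loci, rep("LG?", length(loci)),
                        seq_along(loci) - 1)
  }
  unknown <- setdiff(loci, panel$locus)
  if (length(unknown))
    stop("unknown locus column: ", paste(unknown, collapse = ", "))
  male <- sex == "M"
  if (any(!is.na(a2[male, , drop = FALSE])))
    stop("male calls must carry exactly one allele (a2 set for a male)")
  fem <- !male
  bad <- is.na(a1[fem, , drop = FALSE]) != is.na(a2[fem, , drop = FALSE])
  if (any(bad)) stop("female requires two alleles (half-missing female call)")
  rownames(a1) <- rownames(a2) <- sample_id
  structure(list(panel = panel, sample_id = sample_id, sex = sex,
                 a1 = a1, a2 = a2),
            class = "xstr_dataset")
}

#' @export
print.xstr_dataset <- function(x, ...) {
  cat(sprintf("xstr_dataset: %d samples (%d F, %d M) at %d loci\n",
              length(x$sample_id), sum(x$sex == "F"), sum(x$sex == "M"),
              ncol(x$a1)))
  invisible(x)
}

# Parse one genotype cell. Returns c(a1, a2); a2 NA for males.
parse_call <- function(cell, sex, where) {
  cell <- trimws(cell)
  if (cell == "." || cell == "" || is.na(cell)) return(c(NA, NA))
  parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
  if (sex == "M") {
    if (length(parts) != 1)
      stop("male call must be a single allele at ", where)
    return(c(parts, NA))
  }
  if (length(parts) != 2 || any(!nzchar(parts)))
    stop("female requires two alleles at ", where)
  sort_alleles(parts)[1:2] -> p
  c(p[1], p[2])
}

format_call <- function(a1, a2, sex) {
  if (is.na(a1)) return(".")
  if (sex == "M") as.character(a1) else paste(a1, a2, sep = "/")
}

#' Read a sex-aware genotype table
#'
#' Tab-separated, `#` comments, header `sample_id sex <locus...>`.
#' Cells: males one allele token, females `a/b`, missing `.`.
#'
#' @param path file path.
#' @param panel optional [xstr_panel()]; locus columns must be a subset of
#'   its loci. Without a panel, a bare single-group panel is built from the
#'   header.
#' @return An [xstr_dataset()].
#' @export
read_genotype_table <- function(path, panel = NULL) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  if (!all(c("sample_id", "sex") %in% names(d)))
    stop("genotype table must start with columns sample_id and sex")
  loci <- setdiff(names(d), c("sample_id", "sex"))
  if (!is.null(panel)) {
    unknown <- setdiff(loci, panel$locus)
    if (length(unknown))
      stop("unknown locus column: ", paste(unknown, collapse = ", "))
  }
  sex <- toupper(d$sex)
  ok <- sex %in% c("M", "F")
  if (any(!ok))
    stop("malformed sex code '", d$sex[which(!ok)[1]], "' in row ",
         which(!ok)[1])
  n <- nrow(d)
  a1 <- matrix(NA_character_, n, length(loci), dimnames = list(NULL, loci))
  a2 <- a1
  for (l in loci) {
    for (i in seq_len(n)) {
      call <- parse_call(d[[l]][i], sex[i],
                         sprintf("row %d (sample %s), column %s",
                                 i, d$sample_id[i], l))
      a1[i, l] <- call[1]; a2[i, l] <- call[2]
    }
  }
  xstr_dataset(panel, d$sample_id, sex, a1, a2)
}

#' Write a genotype table
#'
#' Inverse of [read_genotype_table()]; bit-stable for identical input.
#'
#' @param ds an [xstr_dataset()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(ds, path) {
  loci <- colnames(ds$a1)
  cells <- vapply(seq_along(ds$sample_id), function(i) {
    vapply(loci, function(l) format_call(ds$a1[i, l], ds$a2[i, l], ds$sex[i]),
           "")
  }, character(length(loci)))
  out <- data.frame(sample_id = ds$sample_id, sex = ds$sex,
                    t(matrix(cells, nrow = length(loci))),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c("sample_id", "sex", loci)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Chromosomes sampled per locus
#'
#' Each non-missing male call contributes one chromosome, each female call
#' two. At fully typed loci this equals `#males + 2 * #females`.
#'
#' @param ds an [xstr_dataset()].
#' @return Named integer vector over loci.
#' @export
n_chromosomes <- function(ds) {
  male <- ds$sex == "M"
  m <- colSums(!is.na(ds$a1[male, , drop = FALSE]))
  f <- colSums(!is.na(ds$a1[!male, , drop = FALSE]))
  m + 2L * f
}
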