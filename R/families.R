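#' Typed pedigree with X-STR genotypes
#'
#' A family is a small pedigree in which maternal X transmission is the unit
#' of analysis. Two designs are recognised: `three_generation` (a typed
#' grandfather anchors the phase of his daughter, who has one or more
#' children) and `two_generation` (father, mother and offspring; the father
#' may be untyped when all offspring are male).
#'
#' @param family_id family identifier.
#' @param members data frame with columns `individual_id`, `father_id`,
#'   `mother_id`, `sex` (`"M"`/`"F"`); `"0"` marks an absent/untyped parent.
#' @param a1,a2 character matrices (members x loci) of allele labels, rows
#'   in `members` order; males carry `NA` in `a2`.
#' @return An object of class `xstr_family` with a derived `family_type`.
#' @export
xstr_family <- function(family_id, members, a1, a2) {
  need <- c("individual_id", "father_id", "mother_id", "sex")
  if (!all(need %in% names(members)))
    stop("members needs columns: ", paste(need, collapse = ", "))
  members[need] <- lapply(members[need], as.character)
  members$sex <- toupper(members$sex)
  if (!all(members$sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (anyDuplicated(members$individual_id))
    stop("duplicate individual_id in family ", family_id)
  ids <- members$individual_id
  if ("0" %in% ids) stop("'0' is reserved for an untyped parent")
  for (col in c("father_id", "mother_id")) {
    ref <- members[[col]]
    missing_ref <- ref != "0" & !(ref %in% ids)
    if (any(missing_ref))
      stop("family ", family_id, ": referenced parent ",
           ref[missing_ref][1], " not present (use '0' for untyped)")
  }
  # parent sexes
  pa <- members$father_id[members$father_id != "0"]
  if (!all(members$sex[match(pa, ids)] == "M"))
    stop("family ", family_id, ": father_id points to a female")
  ma <- members$mother_id[members$mother_id != "0"]
  if (!all(members$sex[match(ma, ids)] == "F"))
    stop("family ", family_id, ": mother_id points to a male")
  # acyclicity via iterated founder stripping
  left <- ids
  repeat {
    drop <- left[vapply(left, function(i) {
      r <- members[match(i, ids), ]
      !(r$father_id %in% left) && !(r$mother_id %in% left)
    }, TRUE)]
    if (!length(drop)) break
    left <- setdiff(left, drop)
  }
  if (length(left)) stop("cyclic parentage in family ", family_id)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  if (nrow(a1) != nrow(members)) stop("genotype rows must match members")
  rownames(a1) <- rownames(a2) <- ids
  male <- members$sex == "M"
  if (any(!is.na(a2[male, , drop = FALSE])))
    stop("male members must be hemizygous (single allele)")
  fam <- structure(list(family_id = as.character(family_id),
                        members = members, a1 = a1, a2 = a2,
                        loci = colnames(a1)),
                   class = "xstr_family")
  fam$family_type <- family_type(fam)
  fam
}

# A family is three_generation when some child's mother has her own typed
# father in the family (the anchoring grandfather).
family_type <- function(fam) {
  m <- fam$members
  kids <- m$mother_id != "0"
  mothers <- unique(m$mother_id[kids])
  for (mo in mothers) {
    gf <- m$father_id[match(mo, m$individual_id)]
    if (gf != "0") return("three_generation")
  }
  "two_generation"
}

#' @export
print.xstr_family <- function(x, ...) {
  cat(sprintf("xstr_family %s (%s): %d members, %d loci\n", x$family_id,
              x$family_type, nrow(x$members), length(x$loci)))
  invisible(x)
}

# genotype of one member at one locus: males length-1, females length-2,
# NULL when missing.
member_geno <- function(fam, id, locus) {
  a1 <- fam$a1[id, locus]
  if (is.na(a1)) return(NULL)
  if (fam$members$sex[match(id, fam$members$individual_id)] == "M") a1
  else c(a1, fam$a2[id, locus])
}

#' Read a pedigree file
#'
#' PED-like tab-separated dialect with a header line:
#' `family_id individual_id father_id mother_id sex phenotype <locus...>`.
#' Sex is `M`/`F` (or PED's `1`/`2`), `0` marks an untyped parent, the
#' phenotype column is carried but ignored. Genotype cells follow the
#' genotype-table convention (males one allele, females `a/b`, missing `.`).
#' Every child (a member with `mother_id != 0`) must have a typed mother in
#' the file: maternal X transmission is the unit of analysis.
#'
#' @param path file path.
#' @param panel optional [xstr_panel()] used to check locus columns.
#' @return List of [xstr_family()] objects, named by family id.
#' @export
read_pedigree_file <- function(path, panel = NULL) {
  d <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  lead <- c("family_id", "individual_id", "father_id", "mother_id",
            "sex", "phenotype")
  if (!all(lead %in% names(d)))
    stop("pedigree file must start with columns: ",
         paste(lead, collapse = ", "))
  loci <- setdiff(names(d), lead)
  if (!is.null(panel)) {
    unknown <- setdiff(loci, panel$locus)
    if (length(unknown))
      stop("unknown locus column: ", paste(unknown, collapse = ", "))
  }
  d$sex[d$sex == "1"] <- "M"
  d$sex[d$sex == "2"] <- "F"
  fams <- split(seq_len(nrow(d)), d$family_id)
  out <- lapply(fams, function(rows) {
    sub <- d[rows, , drop = FALSE]
    n <- nrow(sub)
    a1 <- matrix(NA_character_, n, length(loci), dimnames = list(NULL, loci))
    a2 <- a1
    for (l in loci) for (i in seq_len(n)) {
      call <- parse_call(sub[[l]][i], toupper(sub$sex[i]),
                         sprintf("family %s, individual %s, locus %s",
                                 sub$family_id[i], sub$individual_id[i], l))
      a1[i, l] <- call[1]; a2[i, l] <- call[2]
    }
    fam <- xstr_family(sub$family_id[1],
                       sub[c("individual_id", "father_id", "mother_id", "sex")],
                       a1, a2)
    # a terminal child with a father but no mother cannot be analysed:
    # maternal X transmission is the unit of analysis
    m <- fam$members
    is_parent <- m$individual_id %in% c(m$father_id, m$mother_id)
    orphan <- !is_parent & m$mother_id == "0" & m$father_id != "0"
    if (any(orphan))
      stop("family ", fam$family_id, ": child ",
           m$individual_id[orphan][1], " has no typed mother")
    fam
  })
  out[order(names(out))]
}

#' Write families to a pedigree file
#'
#' Inverse of [read_pedigree_file()].
#'
#' @param families list of [xstr_family()] objects.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_pedigree_file <- function(families, path) {
  rows <- do.call(rbind, lapply(families, function(fam) {
    m <- fam$members
    cells <- sapply(fam$loci, function(l)
      vapply(seq_len(nrow(m)), function(i)
        format_call(fam$a1[i, l], fam$a2[i, l], m$sex[i]), ""))
    cells <- matrix(cells, nrow = nrow(m),
                    dimnames = list(NULL, fam$loci))
    cbind(data.frame(family_id = fam$family_id,
                     individual_id = m$individual_id,
                     father_id = m$father_id, mother_id = m$mother_id,
                     sex = m$sex, phenotype = "0",
                     stringsAsFactors = FALSE),
          as.data.frame(cells, stringsAsFactors = FALSE))
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
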