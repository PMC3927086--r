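#' Family cohort container
#'
#' A `family_cohort` bundles the three pieces every analysis stage needs:
#' the pedigree/phenotype table, the genotype matrix, and the SNP map.
#'
#' @param individuals A data frame with columns `id`, `family`, `father`,
#'   `mother` (`"0"` for founders), `sex` (`"male"`/`"female"`) and `status`
#'   (`"affected"`/`"unaffected"`/`"unknown"`).
#' @param genotypes Integer matrix (individuals x SNPs) of copies of the A1
#'   allele (0, 1, 2, or `NA` for missing); row names are individual ids,
#'   column names SNP ids.
#' @param map A data frame with columns `snp`, `chrom`, `pos`, `a1`, `a2`.
#'
#' @return An object of class `family_cohort`: a list with elements
#'   `individuals` (tibble), `genotypes` (matrix) and `map` (tibble).
#' @export
family_cohort <- function(individuals, genotypes, map) {
  individuals <- as_tibble(individuals)
  map <- as_tibble(map)
  need <- c("id", "family", "father", "mother", "sex", "status")
  if (!all(need %in% names(individuals))) {
    abort(paste0("individuals must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(individuals$id)) {
    abort("duplicate individual ids")
  }
  if (!all(individuals$sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'")
  }
  if (!all(individuals$status %in% c("affected", "unaffected", "unknown"))) {
    abort("status must be 'affected', 'unaffected' or 'unknown'")
  }
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(individuals)) {
    abort("genotype rows must match individuals")
  }
  if (ncol(genotypes) != nrow(map)) {
    abort("genotype columns must match the SNP map")
  }
  rownames(genotypes) <- individuals$id
  colnames(genotypes) <- map$snp
  # non-founder parent ids must resolve within the same family
  kids <- individuals$father != "0" | individuals$mother != "0"
  if (any(kids)) {
    key <- paste(individuals$family, individuals$id)
    bad <- kids &
      (!(paste(individuals$family, individuals$father) %in% key) |
       !(paste(individuals$family, individuals$mother) %in% key))
    if (any(bad)) {
      abort(paste0("unresolvable parent ids for: ",
                   paste(head(individuals$id[bad], 5), collapse = ", ")))
    }
  }
  structure(list(individuals = individuals, genotypes = genotypes, map = map),
            class = "family_cohort")
}

#' @export
print.family_cohort <- function(x, ...) {
  ind <- x$individuals
  kids <- is_child(x)
  cat("<family_cohort> ", length(unique(ind$family)), " families, ",
      nrow(ind), " individuals (", sum(kids), " children), ",
      nrow(x$map), " SNPs\n", sep = "")
  cat("  children: ", sum(kids & ind$status == "affected"), " affected / ",
      sum(kids & ind$status == "unaffected"), " unaffected",
      "; sexes M:F = ", sum(kids & ind$sex == "male"), ":",
      sum(kids & ind$sex == "female"), "\n", sep = "")
  invisible(x)
}

#' Identify children and founders
#'
#' @param cohort A [family_cohort()].
#' @return Logical vector along `cohort$individuals`.
#' @export
is_child <- function(cohort) {
  cohort$individuals$father != "0" & cohort$individuals$mother != "0"
}

#' @rdname is_child
#' @export
is_founder <- function(cohort) !is_child(cohort)

#' Subset a cohort
#'
#' @param cohort A [family_cohort()].
#' @param individuals Logical or character selection of individuals.
#' @param snps Logical or character selection of SNPs.
#' @return A [family_cohort()].
#' @export
subset_cohort <- function(cohort, individuals = NULL, snps = NULL) {
  ind <- cohort$individuals
  geno <- cohort$genotypes
  map <- cohort$map
  if (!is.null(individuals)) {
    keep <- if (is.character(individuals)) ind$id %in% individuals else individuals
    ind <- ind[keep, , drop = FALSE]
    geno <- geno[keep, , drop = FALSE]
  }
  if (!is.null(snps)) {
    keep <- if (is.character(snps)) map$snp %in% snps else snps
    map <- map[keep, , drop = FALSE]
    geno <- geno[, keep, drop = FALSE]
  }
  family_cohort(ind, geno, map)
}

# row indices of each individual's father/mother (NA for founders)
parent_index <- function(cohort) {
  ind <- cohort$individuals
  key <- paste(ind$family, ind$id)
  list(
    father = match(paste(ind$family, ind$father), key),
    mother = match(paste(ind$family, ind$mother), key)
  )
}

#' Resample families with replacement
#'
#' Draws `length(unique(family))` families with replacement (or a supplied
#' index vector) and rebuilds the cohort with unique family/individual ids so
#' duplicated families remain distinct clusters.
#'
#' @param cohort A [family_cohort()].
#' @param idx Optional integer vector indexing into `sort(unique(family))`;
#'   defaults to a uniform draw with replacement of the original size.
#' @return A [family_cohort()].
#' @export
resample_families <- function(cohort, idx = NULL) {
  fams <- sort(unique(cohort$individuals$family))
  if (is.null(idx)) idx <- sample.int(length(fams), replace = TRUE)
  rows_by_fam <- split(seq_len(nrow(cohort$individuals)), cohort$individuals$family)
  rows_by_fam <- rows_by_fam[fams]
  take <- rows_by_fam[idx]
  rows <- unlist(take, use.names = FALSE)
  rep_id <- rep(seq_along(idx), lengths(take))
  ind <- cohort$individuals[rows, , drop = FALSE]
  suffix <- paste0(".b", rep_id)
  ind$family <- paste0(ind$family, suffix)
  ind$id <- paste0(ind$id, suffix)
  ind$father <- if_else(ind$father == "0", "0", paste0(ind$father, suffix))
  ind$mother <- if_else(ind$mother == "0", "0", paste0(ind$mother, suffix))
  family_cohort(ind, cohort$genotypes[rows, , drop = FALSE], cohort$map)
}
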