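#' Read a PLINK text PED/MAP pair into a family cohort
#'
#' PED columns: family, individual, father, mother, sex (1 = male,
#' 2 = female), phenotype (2 = affected, 1 = unaffected, 0/-9 = unknown),
#' then two allele columns per SNP. `0 0` (or any allele `0`) is missing.
#' Genotypes are stored as copies of the A1 allele, where A1 is the first
#' non-missing allele encountered for that SNP in file order.
#'
#' @param ped,map Paths to the PED and MAP files.
#' @return A [family_cohort()].
#' @export
read_ped_map <- function(ped, map) {
  stopifnot(file.exists(ped), file.exists(map))
  mp <- readr::read_table(map, col_names = c("chrom", "snp", "cm", "pos"),
                          col_types = "ccdi", progress = FALSE)
  n_snps <- nrow(mp)
  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  expect <- 6L + 2L * n_snps
  if (any(len != expect)) {
    bad <- which(len != expect)[1]
    abort(paste0("PED line ", bad, " has ", len[bad], " fields, expected ", expect))
  }
  m <- do.call(rbind, toks)
  ids <- m[, 2]
  if (anyDuplicated(ids)) {
    bad <- which(duplicated(ids))[1]
    abort(paste0("duplicate individual id at PED line ", bad, ": ", ids[bad]))
  }
  al <- m[, -(1:6), drop = FALSE]
  ok <- al %in% c("A", "C", "G", "T", "1", "2", "0")
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(al)), arr.ind = TRUE)[1, ]
    abort(paste0("invalid allele symbol '", al[bad[1], bad[2]],
                 "' at PED line ", bad[1]))
  }
  a1c <- al[, seq(1, 2 * n_snps, by = 2), drop = FALSE]
  a2c <- al[, seq(2, 2 * n_snps, by = 2), drop = FALSE]
  a1c[a1c == "0"] <- NA; a2c[a2c == "0"] <- NA
  miss <- is.na(a1c) | is.na(a2c)
  a1c[miss] <- NA; a2c[miss] <- NA
  geno <- matrix(NA_integer_, nrow(al), n_snps)
  A1 <- A2 <- rep(NA_character_, n_snps)
  for (j in seq_len(n_snps)) {
    obs <- c(rbind(a1c[, j], a2c[, j]))  # file order within line pairs
    seen <- obs[!is.na(obs)]
    if (length(seen) > 0) {
      A1[j] <- seen[1]
      rest <- setdiff(unique(seen), A1[j])
      if (length(rest) > 1) abort(paste0("SNP ", mp$snp[j], " has >2 alleles"))
      A2[j] <- if (length(rest) == 1) rest else NA_character_
      geno[, j] <- (a1c[, j] == A1[j]) + (a2c[, j] == A1[j])
    }
  }
  sex_code <- m[, 5]
  phe <- m[, 6]
  individuals <- tibble(
    id = ids, family = m[, 1], father = m[, 3], mother = m[, 4],
    sex = dplyr::case_when(sex_code == "1" ~ "male", sex_code == "2" ~ "female",
                           TRUE ~ NA_character_),
    status = dplyr::case_when(phe == "2" ~ "affected", phe == "1" ~ "unaffected",
                              TRUE ~ "unknown")
  )
  if (anyNA(individuals$sex)) abort("PED sex codes must be 1 or 2")
  family_cohort(individuals, geno,
                tibble(snp = mp$snp, chrom = mp$chrom, pos = mp$pos,
                       a1 = A1, a2 = dplyr::coalesce(A2, "0")))
}

#' Write a family cohort as PLINK text PED/MAP
#'
#' @param cohort A [family_cohort()].
#' @param ped,map Output paths.
#' @return Invisibly, the PED path.
#' @export
write_ped_map <- function(cohort, ped, map) {
  ind <- cohort$individuals
  mp <- cohort$map
  readr::write_tsv(tibble(chrom = mp$chrom, snp = mp$snp, cm = 0, pos = mp$pos),
                   map, col_names = FALSE, progress = FALSE)
  g <- cohort$genotypes
  n <- nrow(g); n_snps <- ncol(g)
  al <- matrix("0", n, 2L * n_snps)
  for (j in seq_len(n_snps)) {
    gj <- g[, j]
    a1 <- rep(NA_character_, n); a2 <- a1
    a1[!is.na(gj)] <- if_else(gj[!is.na(gj)] >= 1L, mp$a1[j], mp$a2[j])
    a2[!is.na(gj)] <- if_else(gj[!is.na(gj)] == 2L, mp$a1[j], mp$a2[j])
    a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
    al[, 2L * j - 1L] <- a1
    al[, 2L * j] <- a2
  }
  sex <- if_else(ind$sex == "male", "1", "2")
  phe <- dplyr::case_when(ind$status == "affected" ~ "2",
                          ind$status == "unaffected" ~ "1", TRUE ~ "0")
  lines <- paste(ind$family, ind$id, ind$father, ind$mother, sex, phe,
                 apply(al, 1, paste, collapse = " "))
  writeLines(lines, ped)
  invisible(ped)
}

#' Read a gene annotation table
#'
#' Tab-separated with header; columns `gene`, `chrom`, `start`, `end`
#' (1-based inclusive span).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_gene_annotation <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("gene", "chrom", "start", "end")
  if (!all(need %in% names(x))) {
    abort(paste0("annotation must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(x$start > x$end)) abort("annotation has start > end")
  if (anyDuplicated(x$gene)) abort("duplicate gene symbols in annotation")
  as_tibble(x)
}

#' Read a SNP-gene evidence table
#'
#' Tab-separated with header; one row per (SNP, gene) pair carrying the
#' functional-genomics fields consumed by [score_pair()].
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_evidence_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("snp", "gene", "within_gene", "is_eqtl", "prior_report",
            "expression_diff", "cns_specific", "mouse_cns_model", "pathway_member")
  if (!all(need %in% names(x))) {
    abort(paste0("evidence table must have columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(x[, c("snp", "gene")])) abort("duplicate (snp, gene) keys")
  if (!all(x$prior_report %in% c("none", "related_disorder", "autism"))) {
    abort("prior_report must be none/related_disorder/autism")
  }
  if (!all(x$expression_diff %in% c("none", "lymphoblastoid", "brain"))) {
    abort("expression_diff must be none/lymphoblastoid/brain")
  }
  as_tibble(x)
}

#' Write a results table as TSV
#'
#' Writes any per-record result tibble (association results, score cards,
#' variance results) with a header and full floating-point precision.
#'
#' @param results A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(results, path) {
  if (!is.data.frame(results)) abort("results must be a data frame")
  readr::write_tsv(as_tibble(results), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
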