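#' Gene mapping windows
#'
#' A SNP is paired with the nearest gene within the proximal window (5 kb
#' either side, distance 0 inside the gene span); when no gene is that
#' close, with both the closest upstream and closest downstream genes within
#' the extended window (50 kb).
#'
#' @param proximal,extended Window sizes in bp (`proximal < extended`).
#' @return A list of class `gene_mapping_rules`.
#' @export
gene_mapping_rules <- function(proximal = 5000, extended = 50000) {
  stopifnot(proximal > 0, proximal < extended)
  structure(list(proximal = proximal, extended = extended),
            class = "gene_mapping_rules")
}

#' Map SNPs to related genes
#'
#' Distances use 1-based inclusive gene spans: 0 when the SNP position lies
#' inside the span, otherwise base pairs to the nearer span edge.
#'
#' @param snps Data frame with columns `snp`, `chrom`, `pos`.
#' @param annotation Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @param rules A [gene_mapping_rules()].
#' @return A tibble: `snp`, `gene`, `distance`, `side` (`"within"`,
#'   `"upstream"`, `"downstream"`). SNPs with no pair are absent.
#' @export
map_snp_to_genes <- function(snps, annotation, rules = gene_mapping_rules()) {
  snps <- as_tibble(snps)
  ann <- as_tibble(annotation)
  stopifnot(all(c("snp", "chrom", "pos") %in% names(snps)),
            all(c("gene", "chrom", "start", "end") %in% names(ann)))
  ann$chrom <- as.character(ann$chrom)
  snps$chrom <- as.character(snps$chrom)
  purrr::map_dfr(seq_len(nrow(snps)), function(i) {
    pos <- snps$pos[i]
    g <- ann[ann$chrom == snps$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) return(NULL)
    dist <- if_else(pos >= g$start & pos <= g$end, 0,
                    pmin(abs(pos - g$start), abs(pos - g$end)))
    side <- dplyr::case_when(dist == 0 ~ "within",
                             g$end < pos ~ "upstream",
                             TRUE ~ "downstream")
    near <- dist <= rules$proximal
    if (any(near)) {
      pick <- which(near & dist == min(dist[near]))  # ties: all tied genes
      return(tibble(snp = snps$snp[i], gene = g$gene[pick],
                    distance = dist[pick], side = side[pick]))
    }
    out <- NULL
    for (sd in c("upstream", "downstream")) {
      cand <- which(side == sd & dist <= rules$extended)
      if (length(cand) > 0) {
        pick <- cand[which.min(dist[cand])]
        out <- bind_rows(out, tibble(snp = snps$snp[i], gene = g$gene[pick],
                                     distance = dist[pick], side = sd))
      }
    }
    out
  })
}

#' Score a SNP-gene evidence profile
#'
#' Point allocation over four capped categories:
#' \itemize{
#'   \item Statistical (max 2): 1 point if the family-based GWAS p-value is
#'     below 1e-8, 0.5 if in \[1e-8, 1e-5); plus 1 point if the sibling
#'     case-control odds ratio for the risk allele is at least 1.5.
#'   \item Genomic (max 2): 1 point if the SNP lies within the gene
#'     (including 5 kb up/downstream); plus 1 point if the SNP is an eQTL of
#'     the gene.
#'   \item Previous reporting (max 1): 1 point for a prior autism
#'     association, 0.5 for a related neurodevelopmental disorder.
#'   \item Physiological (max 4): 1 point for differential expression in
#'     autism brain (0.5 for lymphoblastoid cell lines); plus 1 each for a
#'     CNS-specific role, a mouse model with CNS impairment, and membership
#'     of an autism-associated pathway.
#' }
#' The maximum total is 9; a pair is selected when the total reaches the
#' cutoff (default 4, closed bound). Boundary bands are half-open with the
#' stricter side winning: p exactly 1e-8 earns 0.5, p exactly 1e-5 earns 0.
#'
#' @param profile Data frame (one or more rows) with columns `gwas_p`,
#'   `sibling_or`, `within_gene`, `is_eqtl`, `prior_report`
#'   (`none`/`related_disorder`/`autism`), `expression_diff`
#'   (`none`/`lymphoblastoid`/`brain`), `cns_specific`, `mouse_cns_model`,
#'   `pathway_member`.
#' @param cutoff Selection cutoff (total >= cutoff).
#' @return The input with appended columns `statistical_points`,
#'   `genomic_points`, `previous_points`, `physiological_points`, `total`,
#'   `selected`.
#' @export
score_pair <- function(profile, cutoff = 4) {
  p <- as_tibble(profile)
  stopifnot(all(p$gwas_p > 0), all(p$gwas_p <= 1), all(p$sibling_or > 0))
  stopifnot(all(p$prior_report %in% c("none", "related_disorder", "autism")),
            all(p$expression_diff %in% c("none", "lymphoblastoid", "brain")))
  stat <- if_else(p$gwas_p < 1e-8, 1, if_else(p$gwas_p < 1e-5, 0.5, 0)) +
    if_else(p$sibling_or >= 1.5, 1, 0)
  gen <- as.numeric(p$within_gene) + as.numeric(p$is_eqtl)
  prev <- dplyr::case_when(p$prior_report == "autism" ~ 1,
                           p$prior_report == "related_disorder" ~ 0.5,
                           TRUE ~ 0)
  phys <- dplyr::case_when(p$expression_diff == "brain" ~ 1,
                           p$expression_diff == "lymphoblastoid" ~ 0.5,
                           TRUE ~ 0) +
    as.numeric(p$cns_specific) + as.numeric(p$mouse_cns_model) +
    as.numeric(p$pathway_member)
  p$statistical_points <- stat
  p$genomic_points <- gen
  p$previous_points <- prev
  p$physiological_points <- phys
  p$total <- stat + gen + prev + phys
  p$selected <- p$total >= cutoff
  p
}

#' Prioritize candidate SNPs by SNP-gene pair scoring
#'
#' Maps each candidate SNP to its related gene(s), joins the functional
#' evidence (a candidate absent from the evidence table is scored with all
#' functional flags off and reported), derives the within-gene flag from the
#' mapping distance (<= 5 kb scores the point), scores every pair, and
#' selects a SNP when any of its pairs reaches the cutoff. The best-scoring
#' pair per SNP is marked for reporting.
#'
#' @param candidates Output of [select_candidates()] (needs `snp`,
#'   `family_p`, `or`; one row per SNP is used — the smallest family p).
#' @param evidence Evidence table (see [read_evidence_table()]).
#' @param annotation Gene annotation (`gene`, `chrom`, `start`, `end`).
#' @param snp_map SNP positions (`snp`, `chrom`, `pos`).
#' @param cutoff Score cutoff (default 4).
#' @param rules A [gene_mapping_rules()].
#' @return A tibble of score cards, one row per mapped (snp, gene) pair,
#'   with category points, `total`, `selected` (SNP-level decision) and
#'   `best_pair`.
#' @export
prioritize <- function(candidates, evidence, annotation, snp_map,
                       cutoff = 4, rules = gene_mapping_rules()) {
  cand <- as_tibble(candidates) |>
    group_by(.data$snp) |>
    slice_min(.data$family_p, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("snp", gwas_p = "family_p", sibling_or = "or")
  pairs <- map_snp_to_genes(snp_map[snp_map$snp %in% cand$snp, , drop = FALSE],
                            annotation, rules)
  if (nrow(pairs) == 0) {
    inform("no candidate SNP mapped to any gene")
    return(tibble())
  }
  ev <- as_tibble(evidence)
  prof <- pairs |>
    inner_join(cand, by = "snp") |>
    left_join(ev[, setdiff(names(ev), "within_gene")], by = c("snp", "gene"))
  unmatched <- is.na(prof$prior_report) & is.na(prof$is_eqtl)
  if (any(unmatched)) {
    inform(paste0(sum(unmatched), " mapped pair(s) absent from the evidence ",
                  "table; scored with functional flags off"))
  }
  prof <- prof |>
    mutate(
      within_gene = .data$distance <= rules$proximal,
      is_eqtl = dplyr::coalesce(.data$is_eqtl, FALSE),
      prior_report = dplyr::coalesce(.data$prior_report, "none"),
      expression_diff = dplyr::coalesce(.data$expression_diff, "none"),
      cns_specific = dplyr::coalesce(.data$cns_specific, FALSE),
      mouse_cns_model = dplyr::coalesce(.data$mouse_cns_model, FALSE),
      pathway_member = dplyr::coalesce(.data$pathway_member, FALSE)
    )
  cards <- score_pair(prof, cutoff = cutoff)
  cards |>
    group_by(.data$snp) |>
    mutate(selected = max(.data$total) >= cutoff,
           best_pair = row_number(dplyr::desc(.data$total)) == 1L) |>
    ungroup()
}
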