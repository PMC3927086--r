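#' Genome-wide significance threshold under a Bonferroni correction
#'
#' The conventional genome-wide level divided by the number of genome-wide
#' analyses performed (four in the discovery design: affected both/male/
#' female and unaffected), giving 1.25e-8 by default.
#'
#' @param base Genome-wide level (default 5e-8).
#' @param n_analyses Number of GWA runs corrected for.
#' @return The corrected threshold.
#' @export
genome_wide_threshold <- function(base = 5e-8, n_analyses = 4) {
  stopifnot(base > 0, n_analyses >= 1)
  base / n_analyses
}

#' Pipeline configuration
#'
#' Aggregates every stage's settings. Either supply `simulate` (parameter
#' lists for [sim_params()] under `discovery` and `validation`, plus
#' `evidence = list(p_true, p_false)`) or `paths` to PED/MAP, annotation and
#' evidence files.
#'
#' @param simulate `NULL`, or a list with elements `discovery`, `validation`
#'   (argument lists for [sim_params()]; `validation` may be `NULL`) and
#'   `evidence`.
#' @param paths `NULL`, or a list with `discovery_ped`, `discovery_map`,
#'   `validation_ped`, `validation_map`, `annotation`, `evidence`.
#' @param qc A [qc_thresholds()].
#' @param p_family_max,p_sibling_max Candidate-selection thresholds.
#' @param cutoff Prioritization score cutoff.
#' @param rules A [gene_mapping_rules()].
#' @param liability List with `male` and `female` [liability_params()].
#' @param bootstrap_B Bootstrap replicates for the GRR CI (0 skips).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            qc = qc_thresholds(),
                            p_family_max = 1e-3, p_sibling_max = 0.05,
                            cutoff = 4, rules = gene_mapping_rules(),
                            liability = default_liability_params(),
                            bootstrap_B = 1000, seed = 1) {
  if (is.null(simulate) && is.null(paths)) {
    abort("either 'simulate' or 'paths' must be given")
  }
  structure(list(simulate = simulate, paths = paths, qc = qc,
                 p_family_max = p_family_max, p_sibling_max = p_sibling_max,
                 cutoff = cutoff, rules = rules, liability = liability,
                 bootstrap_B = bootstrap_B, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [pipeline_config()]
#'   (threshold and rule objects given as plain lists of their fields,
#'   liability as `K`/`K_R` pairs per sex).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(
    simulate = y$simulate, paths = y$paths,
    qc = do.call(qc_thresholds, y$qc %||% list()),
    rules = do.call(gene_mapping_rules, y$rules %||% list())
  )
  if (!is.null(y$liability)) {
    args$liability <- list(
      male = liability_params(y$liability$male$K, y$liability$male$K_R),
      female = liability_params(y$liability$female$K, y$liability$female$K_R)
    )
  }
  for (k in c("p_family_max", "p_sibling_max", "cutoff", "bootstrap_B", "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(pipeline_config, args)
}

#' Run the full prioritization and genetic-score pipeline
#'
#' Stages, in order: simulate or read the cohorts; Mendel masking and SNP QC
#' on each cohort (restricting both to the SNPs passing in both); the
#' family-based GWAS on the discovery cohort (3 models x 4 strata); sibling
#' case-control tests for family hits; candidate selection; SNP-gene
#' prioritization scoring; per-sex best-fitted genetic model selection on
#' the discovery cohort; evaluation of the resulting genetic scores on the
#' validation cohort (GRR, AUC, liability variance explained); and a
#' family-bootstrap CI on each GRR. Every stage writes a TSV under
#' `out_dir` and appends a log line with counts; rerunning with the same
#' configuration is reproducible.
#'
#' @param config A [pipeline_config()] or a path to a YAML config.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list of all stage artifacts.
#' @export
run_pipeline <- function(config, out_dir = tempfile("famscore_run")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logln <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
    inform(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline halted at stage '", name, "': ",
                   conditionMessage(e)))
    })
  }
  yaml::write_yaml(unclass_config(config), file.path(out_dir, "config.yaml"))
  art <- new.env(parent = emptyenv())

  # --- cohorts ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    stage("simulate", {
      dpar <- do.call(sim_params, modifyList(config$simulate$discovery %||% list(),
                                             list(seed = config$seed)))
      disc <- simulate_families(dpar)
      vali <- NULL
      if (!is.null(config$simulate$validation)) {
        vpar <- do.call(sim_params,
                        modifyList(config$simulate$validation,
                                   list(seed = config$seed + 1L)))
        vali <- simulate_families(vpar)
      }
      causal_ids <- disc$map$snp[dpar$causal$snp]
      ev <- config$simulate$evidence %||% list(p_true = 0.8, p_false = 0.1)
      evidence <- simulate_evidence(disc, causal_ids, ev$p_true, ev$p_false,
                                    seed = config$seed + 2L)
      annotation <- simulate_annotation(evidence, disc$map,
                                        seed = config$seed + 3L)
      art$discovery <- disc; art$validation <- vali
      art$evidence <- evidence; art$annotation <- annotation
      logln("simulate: ", length(unique(disc$individuals$family)),
            " discovery families, ",
            if (is.null(vali)) 0 else length(unique(vali$individuals$family)),
            " validation families, ", nrow(disc$map), " SNPs")
    })
  } else {
    stage("read", {
      p <- config$paths
      art$discovery <- read_ped_map(p$discovery_ped, p$discovery_map)
      art$validation <- if (!is.null(p$validation_ped)) {
        read_ped_map(p$validation_ped, p$validation_map)
      }
      art$evidence <- read_evidence_table(p$evidence)
      art$annotation <- read_gene_annotation(p$annotation)
      logln("read: ", nrow(art$discovery$individuals), " discovery individuals")
    })
  }
  write_results_table(art$evidence, file.path(out_dir, "evidence.tsv"))
  write_results_table(art$annotation, file.path(out_dir, "annotation.tsv"))

  # --- qc --------------------------------------------------------------
  stage("qc", {
    qc_one <- function(cohort, label) {
      mm <- mendel_mask(cohort)
      qcres <- snp_qc_filter(mm$cohort, config$qc)
      logln("qc[", label, "]: ", nrow(mm$errors), " Mendel-error family-SNPs ",
            "masked; ", sum(!qcres$report$pass), "/", nrow(qcres$report),
            " SNPs removed")
      qcres
    }
    d <- qc_one(art$discovery, "discovery")
    art$qc_report <- d$report
    art$discovery <- d$cohort
    if (!is.null(art$validation)) {
      v <- qc_one(art$validation, "validation")
      art$qc_report_validation <- v$report
      common <- intersect(d$cohort$map$snp, v$cohort$map$snp)
      art$discovery <- subset_cohort(d$cohort, snps = common)
      art$validation <- subset_cohort(v$cohort, snps = common)
    }
    write_results_table(art$qc_report, file.path(out_dir, "qc_report.tsv"))
  })

  # --- family GWAS -----------------------------------------------------
  stage("fbat", {
    art$family_results <- run_family_gwas(art$discovery)
    write_results_table(art$family_results, file.path(out_dir, "fbat_results.tsv"))
    logln("fbat: ", nrow(art$family_results), " tests (",
          length(unique(art$family_results$snp)), " SNPs x 3 models x 4 strata)")
  })

  # --- sibling GEE + selection ----------------------------------------
  stage("select", {
    hits <- filter(art$family_results, .data$p < config$p_family_max)
    art$sibling_results <- if (nrow(hits) > 0) {
      run_sibling_tests(art$discovery, hits)
    } else {
      tibble(snp = character(), model = character(), sex = character(),
             risk_allele = character(), or = double(), sibling_p = double(),
             non_estimable = logical())
    }
    art$candidates <- select_candidates(art$family_results,
                                         art$sibling_results,
                                         config$p_family_max,
                                         config$p_sibling_max)
    write_results_table(art$sibling_results, file.path(out_dir, "sibling_results.tsv"))
    write_results_table(art$candidates, file.path(out_dir, "candidates.tsv"))
    logln("select: ", nrow(hits), " family hits -> ",
          length(unique(art$candidates$snp)), " candidate SNPs")
  })

  # --- prioritization --------------------------------------------------
  stage("score", {
    art$score_cards <- if (nrow(art$candidates) > 0) {
      prioritize(art$candidates, art$evidence, art$annotation,
                 art$discovery$map, cutoff = config$cutoff,
                 rules = config$rules)
    } else tibble()
    if (nrow(art$score_cards) > 0) {
      write_results_table(art$score_cards, file.path(out_dir, "score_cards.tsv"))
    }
    nsel <- if (nrow(art$score_cards) > 0) {
      length(unique(art$score_cards$snp[art$score_cards$selected]))
    } else 0
    logln("score: ", nsel, " SNPs at score >= ", config$cutoff)
  })

  # --- genetic score build + evaluation, per sex -----------------------
  stage("gs-eval", {
    if (nrow(art$score_cards) == 0 ||
        !any(art$score_cards$selected)) {
      abort("no prioritized SNPs to build a genetic score from")
    }
    if (is.null(art$validation)) {
      abort("no validation cohort configured")
    }
    sel_snp <- unique(art$score_cards$snp[art$score_cards$selected])
    snp_set <- art$candidates |>
      filter(.data$snp %in% sel_snp) |>
      group_by(.data$snp) |>
      slice_min(.data$family_p, n = 1, with_ties = FALSE) |>
      ungroup() |>
      select("snp", "risk_allele")
    for (sx in c("male", "female")) {
      gsm <- select_best_model(art$discovery, snp_set, sx)
      art[[paste0("gs_model_", sx)]] <- gsm
      if (nrow(gsm) == 0) {
        logln("gs-eval[", sx, "]: no admissible SNP after direction filter")
        next
      }
      write_results_table(gsm, file.path(out_dir, paste0("gs_model_", sx, ".tsv")))
      vr <- evaluate_gs(art$validation, gsm, config$liability[[sx]])
      art[[paste0("variance_", sx)]] <- vr
      write_results_table(vr, file.path(out_dir, paste0("variance_", sx, ".tsv")))
      logln("gs-eval[", sx, "]: ", nrow(gsm), " SNPs, GRR = ",
            format(vr$grr, digits = 3), " (p = ", format(vr$p, digits = 2),
            "), AUC = ", format(vr$auc, digits = 3),
            ", genetic variance explained = ",
            format(vr$genetic_variance_explained, digits = 3))
      if (config$bootstrap_B > 0) {
        boot <- bootstrap_statistic(
          art$validation,
          function(ch) {
            sc <- compute_gs(ch, gsm)
            sc <- sc[sc$status %in% c("affected", "unaffected"), ]
            df <- tibble(y = as.integer(sc$status == "affected"),
                         gs = sc$gs, family = sc$family)
            gee_logistic(df, y ~ gs, cluster = "family", or_term = "gs")$or
          },
          B = config$bootstrap_B, seed = config$seed + 10L
        )
        art[[paste0("grr_bootstrap_", sx)]] <- boot
        write_results_table(
          tibble(sex = sx, observed = boot$observed, boot_mean = boot$boot_mean,
                 ci_lower = boot$ci[1], ci_upper = boot$ci[2],
                 inflation = boot$inflation, B = boot$B),
          file.path(out_dir, paste0("grr_bootstrap_", sx, ".tsv")))
        logln("bootstrap[", sx, "]: GRR 95% CI [",
              format(boot$ci[1], digits = 3), ", ",
              format(boot$ci[2], digits = 3), "]")
      }
    }
  })
  invisible(as.list(art))
}

# config as plain lists for YAML serialization
unclass_config <- function(config) {
  x <- unclass(config)
  x$qc <- unclass(x$qc)
  x$rules <- unclass(x$rules)
  x$liability <- lapply(x$liability, function(l) list(K = l$K, K_R = l$K_R))
  if (!is.null(x$simulate)) {
    x$simulate <- lapply(x$simulate, function(s) {
      if (is.data.frame(s)) as.list(s) else s
    })
    for (nm in c("discovery", "validation")) {
      if (!is.null(x$simulate[[nm]]$causal) &&
          is.data.frame(x$simulate[[nm]]$causal)) {
        x$simulate[[nm]]$causal <- as.list(x$simulate[[nm]]$causal)
      }
    }
  }
  x
}
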