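#' Default trait pairs for the bivariate twin-model report
#'
#' Twelve pairs per sex: the two puberty-scale waves with each other, each
#' puberty index with same-age BMI, and each with later BMI up to
#' mid-adulthood.
#'
#' @return A tibble with columns `sex`, `trait1`, `trait2`.
#' @export
default_trait_pairs <- function() {
  per_sex <- tibble::tribble(
    ~trait1, ~trait2,
    "pds12", "pds14",
    "pds12", "bmi12",
    "pds14", "bmi14",
    "pds12", "bmi17",
    "pds12", "bmi24",
    "pds14", "bmi17",
    "pds14", "bmi24",
    "pa",    "bmi16",
    "pa",    "bmi17",
    "pa",    "bmi18",
    "pa",    "bmi25",
    "pa",    "bmi35"
  )
  dplyr::bind_rows(
    dplyr::mutate(per_sex, sex = "male", .before = 1),
    dplyr::mutate(per_sex, sex = "female", .before = 1)
  )
}

#' Default baseline-adjusted longitudinal regression specifications
#'
#' Post-puberty BMI on each puberty index, adjusted for the BMI measured
#' at (or nearest) the puberty assessment.
#'
#' @return A tibble with columns `predictor`, `outcome`, `baseline`.
#' @export
default_longitudinal_specs <- function() {
  tibble::tribble(
    ~predictor, ~outcome, ~baseline,
    "pds12",    "bmi17",  "bmi12",
    "pds12",    "bmi24",  "bmi12",
    "pds14",    "bmi17",  "bmi14",
    "pds14",    "bmi24",  "bmi14",
    "pa",       "bmi17",  "bmi16",
    "pa",       "bmi18",  "bmi16",
    "pa",       "bmi25",  "bmi16",
    "pa",       "bmi35",  "bmi16"
  )
}

#' Configure a full pipeline run
#'
#' @param generator A [twin_cohort_config()] used to simulate the cohort
#'   (also supplies the trait schema when `cohort_path` is given).
#' @param cohort_path Optional path to an existing cohort TSV (written by
#'   [write_cohort()]); when given, no cohort is simulated.
#' @param trait_pairs Twin-model trait pairs, as [default_trait_pairs()].
#' @param longitudinal Baseline-adjusted regression specs, as
#'   [default_longitudinal_specs()].
#' @param pgs_outcomes Outcomes for the polygenic-score regressions.
#' @param decomposition_model Twin model used for the reported
#'   decompositions (`"AE"` by default, with ACE fits retained for the
#'   comparison sheet).
#' @param alpha Nominal significance level.
#' @param n_tests_for_bonferroni Number of tests behind the Bonferroni
#'   threshold on the model-comparison sheet.
#' @param n_pcs Principal components adjusted for in PGS models.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the simulated cohort (overrides the
#'   generator's).
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = twin_cohort_config(),
                       cohort_path = NULL,
                       trait_pairs = default_trait_pairs(),
                       longitudinal = default_longitudinal_specs(),
                       pgs_outcomes = c("pds12", "pds14", "pa"),
                       decomposition_model = "AE",
                       alpha = 0.05,
                       n_tests_for_bonferroni = 24,
                       n_pcs = 10,
                       out_dir = "pubertwin-run",
                       seed = NULL) {
  stopifnot(alpha > 0, alpha < 1)
  if (!is.null(seed)) generator$seed <- as.integer(seed)
  known <- generator$traits$trait
  referenced <- unique(c(trait_pairs$trait1, trait_pairs$trait2,
                         longitudinal$predictor, longitudinal$outcome,
                         longitudinal$baseline, pgs_outcomes))
  absent <- setdiff(referenced, known)
  if (length(absent)) {
    stop("configured trait(s) not in the cohort schema: ",
         paste(absent, collapse = ", "))
  }
  structure(
    list(generator = generator, cohort_path = cohort_path,
         trait_pairs = trait_pairs, longitudinal = longitudinal,
         pgs_outcomes = pgs_outcomes,
         decomposition_model = decomposition_model,
         alpha = alpha, n_tests_for_bonferroni = n_tests_for_bonferroni,
         n_pcs = n_pcs, out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> preprocess -> descriptives -> bivariate twin models
#' with AE/ACE comparison -> baseline-adjusted longitudinal regressions ->
#' polygenic-score regressions, writing one CSV per report table plus a
#' machine-readable JSON manifest with the seed, configuration hash and a
#' hash of every output. Rerunning with the same configuration reproduces
#' every file byte for byte.
#'
#' Report rounding follows journal convention: correlations and betas to
#' two decimals, percentages to whole numbers (the CSVs carry full
#' precision; rounding applies to the `*_print` columns).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the cohort, the report tables and the
#'   manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("cohort", {
    if (is.null(config$cohort_path)) {
      ch <- generate_cohort(config$generator)
      write_cohort(ch, file.path(config$out_dir, "cohort.tsv"))
      ch
    } else {
      ch <- read_cohort(config$cohort_path)
      attr(ch, "config") <- config$generator
      ch
    }
  })

  cohort <- stage("preprocess", preprocess_cohort(cohort))

  descriptives <- stage("descriptives", describe_cohort(cohort))

  twin <- stage("twin_models", {
    rows <- lapply(seq_len(nrow(config$trait_pairs)), function(i) {
      spec <- config$trait_pairs[i, ]
      t1 <- paste0(spec$trait1, "_adj")
      t2 <- paste0(spec$trait2, "_adj")
      fit_ae <- tryCatch(
        fit_bivariate(cohort, t1, t2, model = config$decomposition_model,
                      sex = spec$sex),
        error = function(e) e
      )
      fit_ace <- tryCatch(
        fit_bivariate(cohort, t1, t2, model = "ACE", sex = spec$sex),
        error = function(e) e
      )
      if (inherits(fit_ae, "error")) {
        return(tibble::tibble(sex = spec$sex, trait1 = spec$trait1,
                              trait2 = spec$trait2, status = "fit_failed",
                              error = conditionMessage(fit_ae)))
      }
      co <- fit_ae$correlations
      dec <- fit_ae$decomposition
      pa <- dec$percent[dec$component == "A"]
      pe <- dec$percent[dec$component == "E"]
      cmp <- if (inherits(fit_ace, "error")) NULL else
        tryCatch(compare_models(fit_ace, fit_ae), error = function(e) NULL)
      tibble::tibble(
        sex = spec$sex, trait1 = spec$trait1, trait2 = spec$trait2,
        status = "ok", error = NA_character_,
        r = co$r_phenotypic$estimate,
        r_low = co$r_phenotypic$lower, r_high = co$r_phenotypic$upper,
        r_a = co$rA$estimate, r_a_low = co$rA$lower, r_a_high = co$rA$upper,
        pct_r_a = pa,
        r_e = co$rE$estimate, r_e_low = co$rE$lower, r_e_high = co$rE$upper,
        pct_r_e = pe,
        n_pairs_mz = fit_ae$n_pairs[["MZ"]], n_pairs_dz = fit_ae$n_pairs[["DZ"]],
        loglik_ae = fit_ae$loglik,
        lrt_ace_vs_ae = if (is.null(cmp)) NA_real_ else cmp$lrt_statistic,
        lrt_df = if (is.null(cmp)) NA_integer_ else cmp$df,
        lrt_p = if (is.null(cmp)) NA_real_ else cmp$p_value
      )
    })
    dplyr::bind_rows(rows)
  })

  bonf <- bonferroni_threshold(config$alpha, config$n_tests_for_bonferroni)
  comparison <- stage("model_comparison", {
    ok <- twin[twin$status == "ok", , drop = FALSE]
    tibble::tibble(
      sex = ok$sex, trait1 = ok$trait1, trait2 = ok$trait2,
      lrt = ok$lrt_ace_vs_ae, df = ok$lrt_df, p_value = ok$lrt_p,
      significant_nominal = !is.na(ok$lrt_p) & ok$lrt_p < config$alpha,
      bonferroni_threshold = bonf,
      significant_bonferroni = !is.na(ok$lrt_p) & ok$lrt_p < bonf
    )
  })

  longitudinal <- stage("longitudinal", {
    grid <- merge(config$longitudinal, data.frame(sex = c("male", "female")))
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      res <- tryCatch(
        standardized_association(
          cohort, predictor = paste0(g$predictor, "_adj"),
          outcome = paste0(g$outcome, "_adj"),
          adjust_for = paste0(g$baseline, "_adj"), sex = g$sex),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        return(tibble::tibble(sex = g$sex, predictor = g$predictor,
                              outcome = g$outcome, baseline = g$baseline,
                              status = "fit_failed",
                              error = conditionMessage(res)))
      }
      tibble::tibble(sex = g$sex, predictor = g$predictor,
                     outcome = g$outcome, baseline = g$baseline,
                     status = "ok", error = NA_character_,
                     beta = res$standardized_beta,
                     ci_low = res$ci_low, ci_high = res$ci_high,
                     p_value = res$p_value, n = res$n_individuals)
    })
    dplyr::bind_rows(rows)
  })

  pgs_table <- stage("pgs", {
    if (!nrow(config$generator$pgs)) return(tibble::tibble())
    grid <- expand.grid(pgs = config$generator$pgs$pgs,
                        outcome = config$pgs_outcomes,
                        sex = c("male", "female"),
                        stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      g <- grid[i, ]
      res <- tryCatch(
        pgs_association(cohort, pgs_name = g$pgs,
                        outcome = paste0(g$outcome, "_adj"),
                        n_pcs = config$n_pcs, sex = g$sex),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        return(tibble::tibble(sex = g$sex, pgs = g$pgs, outcome = g$outcome,
                              status = "fit_failed",
                              error = conditionMessage(res)))
      }
      tibble::tibble(sex = g$sex, pgs = g$pgs, outcome = g$outcome,
                     status = "ok", error = NA_character_,
                     n = res$n_individuals, beta = res$standardized_beta,
                     ci_low = res$ci_low, ci_high = res$ci_high,
                     p_value = res$p_value)
    })
    dplyr::bind_rows(rows)
  })

  tables <- list(descriptives = descriptives,
                 twin_models = round_print_cols(twin),
                 model_comparison = comparison,
                 longitudinal = round_print_cols(longitudinal),
                 pgs = round_print_cols(pgs_table))
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(config$out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p, na = "")
    paths[nm] <- p
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pubertwin")),
    seed = config$generator$seed,
    config_hash = rlang::hash(config),
    cohort_hash = rlang::hash(as.data.frame(cohort)),
    bonferroni_threshold = bonf,
    alpha = config$alpha,
    n_tests = config$n_tests_for_bonferroni,
    outputs = lapply(paths, function(p) rlang::hash(readr::read_file(p)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, tables = tables, manifest = manifest,
                 paths = c(paths, manifest = manifest_path)))
}

# Journal-style printed columns: correlations/betas to 2 decimals,
# percentages to whole numbers; estimates keep full precision.
round_print_cols <- function(tab) {
  if (!nrow(tab)) return(tab)
  for (nm in names(tab)) {
    if (grepl("^(r|r_a|r_e|beta|ci_low|ci_high|r_low|r_high|r_a_low|r_a_high|r_e_low|r_e_high)$", nm)) {
      tab[[paste0(nm, "_print")]] <- sprintf("%.2f", tab[[nm]])
    }
    if (grepl("^pct_", nm)) {
      tab[[paste0(nm, "_print")]] <- sprintf("%.0f", tab[[nm]])
    }
  }
  tab
}
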