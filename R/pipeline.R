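#' Run the full synchrony analysis
#'
#' Orchestrates every stage on a validated dataset: group synchrony and
#' kappa, the dyadic observed/expected table with covariates and the paired
#' t-test, session-level neighbour synchrony, the scan-level NN1 table,
#' dominance ranking, proximity likelihoods, and the five model fits - on
#' the full data and again on the foraging-filtered subset for the analyses
#' the filter applies to (scan filter for the dyad/NN tables, session filter
#' for the session-level model).
#'
#' @param data a [herd_data] object.
#' @param interactions interaction event data.frame, or `NULL`: analyses
#'   needing affiliation or ranks are then skipped with a notice.
#' @param foraging_threshold exclusive foraging-fraction bound
#'   (default 0.80).
#' @param seed_conspecific seed for the random-conspecific draws
#'   (default 1).
#' @param seed_elo seed for the Elo randomizations (default 1).
#' @param n_rand Elo randomizations (default 10000).
#' @param fit_models fit the regression models (default `TRUE`; turn off for
#'   cheap descriptive runs).
#' @return list of class `herd_bundle` with the components named above plus
#'   `filtered` (the same analyses on the low-foraging subset), `manifest`
#'   (seeds, threshold, counts) and `notes`.
#' @export
run_analysis <- function(data, interactions = NULL, foraging_threshold = 0.80,
                         seed_conspecific = 1, seed_elo = 1, n_rand = 10000,
                         fit_models = TRUE) {
  val <- validate_scans(data)
  hard <- val$violations[val$violations$kind != "incomplete_behavior", , drop = FALSE]
  if (nrow(hard) > 0L)
    stop("dataset fails validation with ", nrow(hard),
         " violation(s); first: ", hard$kind[1], " in scan (",
         hard$session_id[1], ", ", hard$scan_index[1], ")")
  data <- drop_incomplete_sessions(data)
  notes <- character()
  out <- list()

  out$group_size <- group_size_summary(data)
  out$group_synchrony <- group_synchrony_summary(data)
  out$kappa <- tryCatch(fleiss_kappa(data), error = function(e) {
    notes <<- c(notes, paste("kappa unavailable:", conditionMessage(e)))
    NULL
  })
  out$budget <- behavior_budget(data)
  out$dyads <- dyad_synchrony_table(data)
  out$t_test <- observed_vs_expected_test(out$dyads)
  out$neighbor_table <- session_neighbor_synchrony(data, seed = seed_conspecific)
  out$proximity <- proximity_likelihood_table(data)

  have_social <- !is.null(interactions)
  if (have_social) {
    roster <- data$individuals$id
    out$affiliation <- build_affiliation(interactions, roster)
    out$dominance <- randomized_elo(interactions, roster, n_rand = n_rand,
                                    seed = seed_elo)
    ranks <- dominance_ranks(out$dominance)
    cov <- dyad_covariates(data$individuals, ranks, out$affiliation)
    out$dyads <- merge(out$dyads, cov, by = c("id_a", "id_b"), sort = TRUE)
    out$proximity <- merge(out$proximity, cov, by = c("id_a", "id_b"),
                           sort = TRUE)
    out$nn_scans <- nn_scan_table(data, out$affiliation, ranks)
  } else {
    notes <- c(notes,
               "no interaction data: affiliation, dominance and the models needing them skipped")
  }

  if (fit_models && have_social) {
    ranks <- dominance_ranks(out$dominance)
    out$foraging_model <- fit_foraging_model(out$budget, ranks, compress = TRUE)
    out$neighbor_model <- fit_neighbor_model(out$neighbor_table)
    out$nn_scan_model <- fit_nn_scan_model(out$nn_scans)
    out$dyadic_lmm_observed <- fit_dyadic_lmm(out$dyads, "observed")
    out$dyadic_lmm_proximity <- fit_dyadic_lmm(out$proximity, "proximity")
  }

  # foraging-filtered variants of analyses (ii)-(iii)
  fs <- filter_scans(data, foraging_threshold)
  fsess <- filter_sessions(data, foraging_threshold)
  flt <- list(n_scans_excluded = fs$n_excluded,
              n_scans_retained = fs$n_retained,
              n_sessions_retained = fsess$n_retained_sessions,
              n_sessions_excluded = fsess$n_excluded_sessions)
  flt$group_synchrony <- group_synchrony_summary(fsess$data)
  flt$dyads <- dyad_synchrony_table(fs$data)
  flt$neighbor_table <- session_neighbor_synchrony(fsess$data,
                                                   seed = seed_conspecific)
  if (have_social) {
    ranks <- dominance_ranks(out$dominance)
    cov <- dyad_covariates(data$individuals, ranks, out$affiliation)
    flt$dyads <- merge(flt$dyads, cov, by = c("id_a", "id_b"), sort = TRUE)
    flt$nn_scans <- nn_scan_table(fs$data, out$affiliation, ranks)
    if (fit_models) {
      flt$neighbor_model <- fit_neighbor_model(flt$neighbor_table)
      flt$nn_scan_model <- fit_nn_scan_model(flt$nn_scans)
      flt$dyadic_lmm_observed <- fit_dyadic_lmm(flt$dyads, "observed")
    }
  }
  out$filtered <- flt

  out$manifest <- list(
    package_version = as.character(utils::packageVersion("herdsync")),
    seed_conspecific = seed_conspecific, seed_elo = seed_elo,
    n_rand = n_rand, foraging_threshold = foraging_threshold,
    n_individuals = nrow(data$individuals),
    n_sessions = length(unique(data$scans$session_id)),
    n_scans = nrow(scan_keys(data)), n_dyads = nrow(out$dyads))
  out$notes <- notes
  structure(out, class = "herd_bundle")
}

#' @export
print.herd_bundle <- function(x, ...) {
  m <- x$manifest
  cat("<herd_bundle> ", m$n_individuals, " individuals, ", m$n_sessions,
      " sessions, ", m$n_scans, " scans, ", m$n_dyads, " dyads\n", sep = "")
  cat(sprintf("group synchrony: mean %.2f%%; thresholds %s\n",
              x$group_synchrony$mean,
              paste(sprintf("%s: %.1f%%", names(x$group_synchrony$threshold_props),
                            100 * x$group_synchrony$threshold_props),
                    collapse = ", ")))
  if (!is.null(x$kappa))
    cat(sprintf("Fleiss kappa: %.3f on %d complete scans\n",
                x$kappa$K, x$kappa$n_subjects))
  cat(sprintf("dyadic synchrony: observed %.2f%% vs expected %.2f%% (t = %.2f, df = %d)\n",
              100 * x$t_test$mean_observed, 100 * x$t_test$mean_expected,
              x$t_test$t, x$t_test$df))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Write an analysis bundle to disk
#'
#' Tables go to CSV, scalar summaries and the manifest to JSON, under `dir`.
#'
#' @param bundle a `herd_bundle` from [run_analysis()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  wcsv(bundle$budget, "behavior_budget")
  wcsv(bundle$dyads, "dyad_synchrony")
  wcsv(bundle$neighbor_table, "session_neighbor_synchrony")
  wcsv(bundle$proximity, "proximity_likelihood")
  if (!is.null(bundle$nn_scans)) wcsv(bundle$nn_scans, "nn_scan_table")
  if (!is.null(bundle$dominance)) wcsv(bundle$dominance$scores, "dominance")
  for (nm in c("foraging_model", "neighbor_model", "nn_scan_model",
               "dyadic_lmm_observed", "dyadic_lmm_proximity")) {
    if (!is.null(bundle[[nm]])) wcsv(bundle[[nm]]$coefficients, paste0(nm, "_coefficients"))
  }
  summ <- list(
    manifest = bundle$manifest,
    group_size = bundle$group_size[c("mean", "min", "max", "sd", "n_scans")],
    group_synchrony = list(mean = bundle$group_synchrony$mean,
                           sd = bundle$group_synchrony$sd,
                           threshold_props = as.list(bundle$group_synchrony$threshold_props)),
    kappa = if (!is.null(bundle$kappa)) unclass(bundle$kappa)[c(
      "K", "P_bar", "Pe_bar", "n_subjects", "n_raters", "n_categories")],
    t_test = bundle$t_test,
    filtered_counts = bundle$filtered[c("n_scans_excluded", "n_scans_retained",
                                        "n_sessions_retained", "n_sessions_excluded")],
    notes = bundle$notes)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(dir)
}

#' Simulate, analyse, and check recovery end to end
#'
#' @param config a [sim_config].
#' @param n_rand Elo randomizations for the check (default 1000; the check
#'   needs stable ranks, not converged scores).
#' @return list: `report` (from [truth_report()]), `pass` (all checks
#'   passed), `bundle`.
#' @export
run_end_to_end_check <- function(config = sim_config(), n_rand = 1000) {
  sim <- simulate_herd(config)
  bundle <- run_analysis(sim$data, sim$interactions,
                         seed_conspecific = config$seed,
                         seed_elo = config$seed, n_rand = n_rand)
  report <- truth_report(sim$truth, bundle)
  list(report = report, pass = all(report$pass), bundle = bundle)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write simulated scan + interaction CSVs),
#' `analyze` (run [run_analysis()] on CSV inputs and write the bundle),
#' `check` (end-to-end recovery check; non-zero exit status on failure).
#' Install target: `inst/cli/herdsync`.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status, invisibly (0 = success).
#' @export
herdsync_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: herdsync <simulate|analyze|check> [options]",
    "  simulate --out DIR [--seed N] [--sessions N]",
    "  analyze  --scans FILE [--interactions FILE] --out DIR",
    "           [--foraging-threshold X] [--seed-conspecific N] [--seed-elo N]",
    "           [--n-rand N]",
    "  check    [--seed N] [--sessions N]", sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]; args <- args[-1]
  opt <- function(flag, default = NULL) {
    i <- match(flag, args)
    if (is.na(i)) default else args[i + 1L]
  }
  status <- 0L
  if (cmd == "simulate") {
    dir <- opt("--out"); if (is.null(dir)) stop("simulate needs --out")
    cfg <- sim_config(seed = as.integer(opt("--seed", "1")),
                      n_sessions = as.integer(opt("--sessions", "128")))
    sim <- simulate_herd(cfg)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_scans(sim$data, file.path(dir, "scans.csv"))
    utils::write.csv(sim$interactions, file.path(dir, "interactions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = cfg$seed, n_sessions = cfg$n_sessions),
                         file.path(dir, "manifest.json"), auto_unbox = TRUE)
    message("wrote ", dir)
  } else if (cmd == "analyze") {
    scans <- opt("--scans"); if (is.null(scans)) stop("analyze needs --scans")
    dir <- opt("--out"); if (is.null(dir)) stop("analyze needs --out")
    inter_path <- opt("--interactions")
    data <- read_scans(scans)
    inter <- if (!is.null(inter_path)) read_interactions(inter_path) else NULL
    bundle <- run_analysis(
      data, inter,
      foraging_threshold = as.numeric(opt("--foraging-threshold", "0.8")),
      seed_conspecific = as.integer(opt("--seed-conspecific", "1")),
      seed_elo = as.integer(opt("--seed-elo", "1")),
      n_rand = as.integer(opt("--n-rand", "10000")))
    write_bundle(bundle, dir)
    message("wrote ", dir)
  } else if (cmd == "check") {
    cfg <- sim_config(seed = as.integer(opt("--seed", "1")),
                      n_sessions = as.integer(opt("--sessions", "128")))
    res <- run_end_to_end_check(cfg)
    print(res$report)
    status <- if (res$pass) 0L else 1L
  } else {
    message(usage); status <- 1L
  }
  invisible(status)
}
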