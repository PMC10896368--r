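#' Run the full synthetic-cohort analysis pipeline
#'
#' End-to-end exercise of every stage on simulated data: cohort generation,
#' QC, per-cohort AT classification, the endpoint (A+T+ vs A-T-) differential
#' abundance in discovery and replication cohorts, three-stage meta-analysis,
#' pseudo-trajectory grouping of the Bonferroni survivors, signature
#' derivation (lasso, correlation pruning, platform restriction, multivariate
#' refit, freeze) with held-out and replication evaluation, and clinical
#' outcome models by predicted signature status. All outputs are written as
#' plain-text TSV/JSON; given the same configuration the run is byte-stable.
#'
#' The first configured cohort is the discovery (stage 1) cohort, the second
#' the replication (stage 2) cohort.
#'
#' @param config a \code{\link{simulation_config}} with at least two cohorts.
#' @param out_dir output directory (created if needed); set NULL to skip
#'   writing.
#' @param ridge_fallback forwarded to \code{\link{freeze_signature}}: when the
#'   unpenalized multivariate refit separates completely (common on synthetic
#'   data whose planted effects are independent across proteins, so the
#'   panel's joint discrimination accumulates unrealistically), fall back to
#'   a lightly ridge-penalized fit instead of aborting (default TRUE here).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with all intermediate objects: \code{sim},
#'   \code{qc}, \code{records}, \code{daa} (per stage), \code{meta},
#'   \code{trajectories}, \code{model}, \code{evals}, \code{progression},
#'   \code{km}.
#' @export
run_pipeline <- function(config, out_dir = NULL, ridge_fallback = TRUE,
                         quiet = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(config$cohorts) < 2) {
    stop("pipeline needs a discovery and a replication cohort", call. = FALSE)
  }
  say <- function(...) if (!quiet) message(...)

  say("simulating cohorts...")
  sim <- simulate_cohorts(config)

  say("running QC...")
  qc <- lapply(sim$datasets, run_qc)
  datasets <- lapply(qc, `[[`, "dataset")

  say("classifying AT status...")
  records <- lapply(config$cohorts, function(co) {
    rec <- sim$records[[co]]
    rec <- rec[rec$sample_id %in% datasets[[co]]$sample_ids, , drop = FALSE]
    ab_cut <- fit_mixture_cut(rec$abeta42, "low-is-positive", seed = config$seed)
    pt_cut <- fit_mixture_cut(rec$ptau, "high-is-positive", seed = config$seed)
    assign_at(rec, ab_cut, pt_cut, quiet = quiet)
  })
  names(records) <- config$cohorts

  stage1_co <- config$cohorts[1]
  stage2_co <- config$cohorts[2]

  say("differential abundance (A+T+ vs A-T-)...")
  daa1 <- run_daa(datasets[[stage1_co]], records[[stage1_co]], "A+T+", "A-T-")
  daa2 <- run_daa(datasets[[stage2_co]], records[[stage2_co]], "A+T+", "A-T-")

  say("three-stage meta-analysis...")
  meta <- run_three_stage(daa1, daa2)
  survivors <- meta$aptamer_id[meta$passes_bonf]
  say(length(survivors), " aptamers pass the Bonferroni gate")

  say("pseudo-trajectory grouping...")
  traj <- run_trajectories(datasets[[stage1_co]], records[[stage1_co]], survivors)

  say("signature derivation...")
  rec1 <- records[[stage1_co]]
  rec1 <- rec1[rec1$at_status %in% c("A+T+", "A-T-"), , drop = FALSE]
  split <- split_train_test(rec1, 0.7, seed = config$seed + 101L)
  log1 <- log10(datasets[[stage1_co]]$rfu)
  candidates <- survivors
  if (length(candidates) < 2) stop("too few Bonferroni survivors to derive a signature", call. = FALSE)
  y_of <- function(ids) as.numeric(rec1$at_status[match(ids, rec1$sample_id)] == "A+T+")
  Xtr_raw <- log1[split$train, candidates, drop = FALSE]
  Xtr <- scale(Xtr_raw)
  sel <- lasso_select(Xtr, y_of(split$train), seed = config$seed + 202L)
  meta_p <- stats::setNames(meta$p_combined, meta$aptamer_id)
  pruned <- prune_correlated(sel$proteins, Xtr_raw, priority_p = meta_p)
  restricted <- restrict_to_platform(pruned, datasets[[stage2_co]]$aptamer_ids)
  model <- freeze_signature(restricted, Xtr_raw, y_of(split$train),
                            ridge_fallback = ridge_fallback, label = stage1_co)
  say("frozen panel: ", length(model$protein_ids), " proteins (lasso ",
      length(sel$proteins), " -> pruned ", length(pruned),
      " -> platform ", length(restricted), ")")

  say("evaluating the frozen model...")
  rec2 <- records[[stage2_co]]
  rec2 <- rec2[rec2$at_status %in% c("A+T+", "A-T-"), , drop = FALSE]
  log2m <- log10(datasets[[stage2_co]]$rfu)
  ev_test <- evaluate(score_samples(model, log1[split$test, , drop = FALSE]),
                      y_of(split$test), threshold = model$cutoff,
                      label = paste0(stage1_co, "_test"))
  ev_rep <- evaluate(score_samples(model, log2m[rec2$sample_id, , drop = FALSE]),
                     as.numeric(rec2$at_status == "A+T+"),
                     threshold = model$cutoff, label = stage2_co)
  evals <- list(stage1_test = ev_test, stage2 = ev_rep)

  say("clinical outcomes by predicted signature status...")
  all_rec <- rbind(records[[stage1_co]], records[[stage2_co]])
  scores <- c(score_samples(model, log1[records[[stage1_co]]$sample_id, , drop = FALSE]),
              score_samples(model, log2m[records[[stage2_co]]$sample_id, , drop = FALSE]))
  all_rec$predicted_status <- as.integer(scores[all_rec$sample_id] >= model$cutoff)
  visits <- rbind(sim$longitudinal[[stage1_co]], sim$longitudinal[[stage2_co]])
  visits <- visits[visits$sample_id %in% all_rec$sample_id, , drop = FALSE]
  progression <- fit_progression(visits, all_rec)
  km <- km_curve(all_rec$followup_years, all_rec$converted,
                 ifelse(all_rec$predicted_status == 1, "signature_positive",
                        "signature_negative"))

  result <- list(sim = sim, qc = lapply(qc, `[[`, "report"), records = records,
                 daa = list(stage1 = daa1, stage2 = daa2), meta = meta,
                 trajectories = traj, lasso = sel, model = model, evals = evals,
                 progression = progression, km = km)

  if (!is.null(out_dir)) {
    say("writing outputs to ", out_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (co in c(stage1_co, stage2_co)) {
      write_qc_report_json(qc[[co]]$report, file.path(out_dir, paste0("qc_", co, ".json")))
      write_table_tsv(records[[co]], file.path(out_dir, paste0("records_", co, ".tsv")))
    }
    write_table_tsv(daa1, file.path(out_dir, "daa_stage1.tsv"))
    write_table_tsv(daa2, file.path(out_dir, "daa_stage2.tsv"))
    write_table_tsv(meta, file.path(out_dir, "meta.tsv"))
    write_table_tsv(traj$calls, file.path(out_dir, "trajectories.tsv"))
    write_signature_json(model, file.path(out_dir, "signature.json"))
    jsonlite::write_json(lapply(evals, unclass), file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_table_tsv(progression$coefficients, file.path(out_dir, "progression.tsv"))
    write_table_tsv(km$curves, file.path(out_dir, "km_curves.tsv"))
  }
  invisible(result)
}
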