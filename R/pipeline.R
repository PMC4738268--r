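#' Default pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @return nested list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    scenarios = c("normoxia", "hypoxia"),
    wells = 500L,
    ensemble_runs = 100L,
    expression = list(n_probes = 20000L, signature_size = 200L,
                      overlap_frac = 0.5, fold = 4, noise_sdlog = 0.1),
    fit = list(tolerance = 3.5, method = "max_z", switch_day = 3,
               kds_axis = c(1e-4, 2e-4, 5e-4, 1e-3, 2e-3, 5e-3,
                            1e-2, 2e-2, 5e-2, 0.1, 0.2, 0.5, 1)),
    overlap = list(alpha = 0.05)
  )
}

# scenario with its seed re-derived from the pipeline master seed
pipeline_scenario <- function(name, master_seed, k) {
  scn <- scenario(name)
  scn$seed <- derive_seed(master_seed, 1000L + k)
  scn$proto$seed <- derive_seed(master_seed, 2000L + k)
  scn
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the stages of the study's computational analysis in
#' dependency order: `synth` (generate the synthetic inputs), `simulate`
#' (deterministic trajectories and SSA ensembles per scenario), `mammosphere`
#' (in-silico sphere rates and the between-condition comparison), `fit`
#' (two-phase dedifferentiation grid fit on the hypoxia time course) and
#' `overlap` (signature derivation and Fisher overlap report). Later stages
#' read the `synth` artifacts from `outdir` and fail with a clear dependency
#' error when they are missing. Every artifact is recorded in
#' `manifest.csv` (path, stage, seed, md5 checksum); re-running with an
#' identical config reproduces identical outputs.
#'
#' @param config nested list as from [default_pipeline_config()], or a path
#'   to a YAML file with the same structure.
#' @param outdir output directory (created if needed).
#' @param stages character vector of stages to run, in any order; executed in
#'   dependency order.
#' @return invisibly, the manifest data.frame.
#' @export
run_pipeline <- function(config = default_pipeline_config(), outdir,
                         stages = c("synth", "simulate", "mammosphere",
                                    "fit", "overlap")) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  order <- c("synth", "simulate", "mammosphere", "fit", "overlap")
  stages <- order[order %in% match.arg(stages, order, several.ok = TRUE)]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  scns <- lapply(seq_along(config$scenarios), function(k) {
    pipeline_scenario(config$scenarios[k], seed, k)
  })
  names(scns) <- config$scenarios

  manifest <- data.frame(path = character(0), stage = character(0),
                         seed = integer(0), md5 = character(0))
  note <- function(path, stage) {
    manifest <<- rbind(manifest, data.frame(
      path = basename(path), stage = stage, seed = seed,
      md5 = unname(tools::md5sum(path))))
  }
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("stage '", stage, "' requires missing upstream artifact: ",
           basename(path), " (run the 'synth' stage first)")
    }
    path
  }
  fail_record <- function(stage, e) {
    fpath <- file.path(outdir, "FAILED.txt")
    writeLines(c(sprintf("stage: %s", stage), sprintf("error: %s",
                                                      conditionMessage(e))),
               fpath)
    note(fpath, stage)
    write_manifest()
    stop(e)
  }
  write_manifest <- function() {
    utils::write.csv(manifest, file.path(outdir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  for (stage in stages) {
    tryCatch({
      if (stage == "synth") {
        for (nm in names(scns)) {
          tc <- generate_timecourse(scns[[nm]])
          p <- file.path(outdir, sprintf("timecourse_%s.csv", nm))
          utils::write.csv(tc$fractions, p, row.names = FALSE, quote = FALSE)
          note(p, stage)
          mc <- generate_mammosphere_counts(scns[[nm]], config$wells)
          p <- file.path(outdir, sprintf("mammosphere_counts_%s.csv", nm))
          utils::write.csv(data.frame(positives = mc[["positives"]],
                                      wells = mc[["wells"]]),
                           p, row.names = FALSE, quote = FALSE)
          note(p, stage)
        }
        ex <- config$expression
        sets <- plant_overlapping_sets(ex$n_probes, ex$signature_size,
                                       ex$overlap_frac,
                                       seed = derive_seed(seed, 3000L))
        spec <- synthetic_expression_spec(
          ex$n_probes,
          conditions = list(condA = list(up = sets$A, fold = ex$fold),
                            condB = list(up = sets$B, fold = ex$fold)),
          noise_sdlog = ex$noise_sdlog,
          seed = derive_seed(seed, 3001L))
        p <- file.path(outdir, "expression.csv")
        write_expression_table(generate_expression(spec), p)
        note(p, stage)
      } else if (stage == "simulate") {
        for (nm in names(scns)) {
          scn <- scns[[nm]]
          times <- seq(0, max(scn$days), by = 0.1)
          traj <- solve_deterministic(population_state(0, S = 0, D = 1000),
                                      scn$params, times)
          p <- file.path(outdir, sprintf("trajectory_%s.csv", nm))
          write_trajectory(traj, p)
          note(p, stage)
          cfg <- ssa_config(t_end = max(scn$days),
                            seed = derive_seed(seed, 4000L + match(nm, names(scns))))
          ens <- simulate_ensemble(population_state(0, S = 0, D = 100),
                                   scn$params, cfg, config$ensemble_runs)
          p <- file.path(outdir, sprintf("ensemble_%s.csv", nm))
          pf <- file.path(outdir, sprintf("ensemble_finals_%s.csv", nm))
          write_ensemble(ens, p, pf)
          note(p, stage); note(pf, stage)
        }
      } else if (stage == "mammosphere") {
        stopifnot(length(scns) >= 2)
        cmp <- compare_conditions(scns[[1]]$assay_params,
                                  scns[[2]]$assay_params,
                                  scns[[1]]$proto)
        for (i in 1:2) {
          res <- if (i == 1) cmp$normoxia else cmp$hypoxia
          p <- file.path(outdir,
                         sprintf("mammosphere_runs_%s.csv", names(scns)[i]))
          utils::write.csv(res$finals, p, row.names = FALSE, quote = FALSE)
          note(p, stage)
        }
        p <- file.path(outdir, "mammosphere_comparison.csv")
        utils::write.csv(data.frame(
          condition = names(scns)[1:2],
          rate = c(cmp$normoxia$rate, cmp$hypoxia$rate),
          ci_lo = c(cmp$normoxia$ci[1], cmp$hypoxia$ci[1]),
          ci_hi = c(cmp$normoxia$ci[2], cmp$hypoxia$ci[2]),
          fisher_p = cmp$p_value), p, row.names = FALSE, quote = FALSE)
        note(p, stage)
      } else if (stage == "fit") {
        hyp <- grep("hypoxia", names(scns), value = TRUE)[1]
        if (is.na(hyp)) stop("fit stage requires a hypoxia scenario")
        tc <- need(file.path(outdir, sprintf("timecourse_%s.csv", hyp)), stage)
        data <- fit_data(utils::read.csv(tc))
        scn <- scns[[hyp]]
        fitcfg <- config$fit
        grid <- grid_spec(alpha_S = scn$params$alpha_S,
                          delta_S = scn$params$delta_S,
                          alpha_D = scn$params$alpha_D,
                          delta_D = scn$params$delta_D,
                          k_SD = scn$params$k_SD,
                          k_DS_early = fitcfg$kds_axis,
                          k_DS_late = fitcfg$kds_axis)
        fit <- fit_two_phase_dedifferentiation(
          grid, data, switch_day = fitcfg$switch_day,
          tolerance = fitcfg$tolerance, method = fitcfg$method)
        p <- file.path(outdir, "fit_hypoxia.txt")
        write_fit_result(fit, p)
        note(p, stage)
      } else if (stage == "overlap") {
        exp_path <- need(file.path(outdir, "expression.csv"), stage)
        tab <- read_expression_table(exp_path, reference = "ref")
        sigA <- derive_signature(tab, "condA", "up")
        sigB <- derive_signature(tab, "condB", "up")
        for (s in list(sigA, sigB)) {
          p <- file.path(outdir, sprintf("signature_up_%s.txt", s$condition))
          write_signature(s, p)
          note(p, stage)
        }
        rep <- overlap_report(list(condA_vs_condB = list(A = sigA, B = sigB)),
                              universe_size = nrow(tab),
                              alpha = config$overlap$alpha)
        p <- file.path(outdir, "overlap_report.csv")
        utils::write.csv(rep, p, row.names = FALSE, quote = FALSE)
        note(p, stage)
      }
    }, error = function(e) fail_record(stage, e))
  }
  write_manifest()
  invisible(manifest)
}
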