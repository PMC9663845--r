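#' Default pipeline configuration
#'
#' A complete, serializable parameterization of one reproducible run:
#' scenario parameters, statistics parameters, and output directory. All
#' defaults mirror the adaptation-experiment analysis (20,000 bootstrap
#' iterations, alpha 0.05, 4-sample persistence, 200-250 ms P2p window,
#' posterior/left/right clusters).
#'
#' @param seed Master seed for the run.
#' @param out_dir Output directory.
#' @param n_boot,alpha,min_run,p2p_window Statistics parameters.
#' @param coupling Brain-behavior coupling of the scenario.
#' @param reject_threshold Peak-to-peak epoch-rejection threshold, microvolts.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = "numadapt_run",
                               n_boot = 20000, alpha = 0.05, min_run = 4,
                               p2p_window = c(200, 250), coupling = 0.6,
                               reject_threshold = 150) {
  structure(
    list(seed = as.integer(seed), out_dir = out_dir,
         scenario = list(coupling = coupling),
         preprocess = list(reject_threshold = reject_threshold),
         stats = list(n_boot = as.integer(n_boot), alpha = alpha,
                      min_run = as.integer(min_run),
                      p2p_window = p2p_window,
                      p1_window = c(80, 140),
                      clusters = electrode_clusters())),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- default_run_config()
  merge_into <- function(base, upd) {
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]]))
        merge_into(base[[k]], upd[[k]]) else upd[[k]]
    }
    base
  }
  structure(merge_into(unclass(cfg), y), class = "run_config")
}

# 31-ary rolling hash (mod 2^31 - 1) of the serialized config, reported in
# every output so a result file can be traced to the configuration that
# produced it
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Simulates one complete experiment under the packaged scenario, writes the
#' behavioral estimate table and per-condition participant-ERP containers,
#' runs the behavioral analysis (pruning, one-way RM-ANOVA with post-hocs,
#' two-way Condition x Numerosity ANOVA on filling numerosities, adaptation
#' magnitudes) and the ERP analysis (point-wise bootstrap contrasts on the
#' posterior, left and right clusters, P2p window amplitudes and their
#' bootstrap distributions, topography differences, brain-behavior
#' correlation), and writes `results.json`, `behavior.json` and a
#' human-readable `summary.txt`. The whole bundle is a pure function of the
#' configuration (including its seed).
#'
#' @param config A `run_config`, as from [default_run_config()].
#' @return Invisibly, a list with the in-memory results (`behavior`,
#'   `contrasts`, `correlation`, `paths`).
#' @export
run_pipeline <- function(config = default_run_config()) {
  stopifnot(inherits(config, "run_config"))
  st <- config$stats
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  logf <- function(...) cat(sprintf(...), "\n", sep = "")

  logf("run %s: simulating scenario (seed %d)", hash, config$seed)
  scenario <- default_adaptation_scenario(coupling = config$scenario$coupling)
  sim <- simulate_experiment(scenario, seed = config$seed)

  est_path <- file.path(config$out_dir, "estimates.csv")
  write_estimates(sim$behavior, est_path)

  erp_paths <- character(0)
  for (cond in names(sim$erps)) {
    s <- sim$erps[[cond]]
    ep <- epoch_set(s$data, 250, s$time_ms, s$channel_names, condition = cond)
    p <- file.path(config$out_dir, paste0("erps_", tolower(cond), ".epo"))
    write_epochs(ep, p)
    erp_paths <- c(erp_paths, p)
  }

  # --- behavioral analysis (central numerosity) ---
  central <- sim$behavior[sim$behavior$numerosity == 30, ]
  pruned <- prune_table(central)
  logf("pruning removed %.1f%% of central-numerosity estimates",
       attr(pruned, "removed_fraction"))
  aov1 <- rm_anova_oneway(pruned)
  mag <- adaptation_magnitude(pruned)
  filling <- sim$behavior[sim$behavior$numerosity != 30 &
                            sim$behavior$condition %in% c("Baseline", "Neutral"), ]
  aov2 <- rm_anova_twoway(prune_table(filling))
  behavior_report <- list(
    config_hash = hash,
    condition_means = as.list(aov1$means),
    removed_fraction = attr(pruned, "removed_fraction"),
    oneway = list(F = aov1$F, df = aov1$df, p = aov1$p,
                  eta_squared = aov1$eta_squared,
                  partial_eta_squared = aov1$partial_eta_squared,
                  posthoc = aov1$posthoc),
    twoway = lapply(aov2$terms, function(t)
      list(F = t$F, df = t$df, p = t$p, eta_squared = t$eta_squared)),
    adaptation_magnitude = mag
  )
  beh_path <- file.path(config$out_dir, "behavior.json")
  jsonlite::write_json(behavior_report, beh_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)

  # --- ERP analysis ---
  pairs <- list(c("Adaptation", "Neutral"), c("Baseline", "Adaptation"),
                c("Baseline", "Neutral"))
  contrasts <- list()
  seed_i <- 0L
  for (pr in pairs) {
    for (cl in names(st$clusters)) {
      seed_i <- seed_i + 1L
      key <- paste0(tolower(pr[1]), "_vs_", tolower(pr[2]), ".", cl)
      res <- contrast_conditions(sim$erps, pr, st$clusters[[cl]],
                                 n_boot = st$n_boot, alpha = st$alpha,
                                 min_run = st$min_run,
                                 seed = config$seed * 1000L + seed_i)
      contrasts[[key]] <- res
      w <- significant_windows(res)
      logf("contrast %s: %d significant window(s)%s", key, nrow(w),
           if (nrow(w)) paste0(" [", paste(sprintf("%g-%g ms", w$start_ms, w$end_ms),
                                           collapse = ", "), "]") else "")
    }
  }

  amp_n <- window_amplitude(sim$erps$Neutral, st$p2p_window, st$clusters$left)
  amp_a <- window_amplitude(sim$erps$Adaptation, st$p2p_window, st$clusters$left)
  amp_n_r <- window_amplitude(sim$erps$Neutral, st$p2p_window, st$clusters$right)
  amp_a_r <- window_amplitude(sim$erps$Adaptation, st$p2p_window, st$clusters$right)
  wb_left <- window_bootstrap_distribution(amp_n, amp_a, n_boot = st$n_boot,
                                           seed = config$seed * 1000L + 101L)
  wb_right <- window_bootstrap_distribution(amp_n_r, amp_a_r, n_boot = st$n_boot,
                                            seed = config$seed * 1000L + 102L)
  corr <- brain_behavior_correlation(mag$difference, amp_n - amp_a)
  topo <- topography_difference(sim$erps, c("Neutral", "Adaptation"),
                                windows = list(st$p1_window, st$p2p_window))

  results <- list(
    config_hash = hash,
    config = unclass(config),
    contrasts = lapply(contrasts, function(r)
      list(time_ms = r$time_ms, mean_diff = r$mean_diff, p_raw = r$p_raw,
           p_fdr = r$p_fdr, sig_mask = r$sig_mask,
           significant_windows = significant_windows(r))),
    p2p_window_amplitude = list(
      left = list(neutral = amp_n, adaptation = amp_a,
                  mean_diff = wb_left$mean_diff, ci = wb_left$ci,
                  null_excluded = wb_left$null_excluded),
      right = list(neutral = amp_n_r, adaptation = amp_a_r,
                   mean_diff = wb_right$mean_diff, ci = wb_right$ci,
                   null_excluded = wb_right$null_excluded)),
    brain_behavior = corr,
    topography = list(windows = colnames(topo), channels = rownames(topo),
                      values = unname(topo))
  )
  res_path <- file.path(config$out_dir, "results.json")
  jsonlite::write_json(results, res_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)

  # --- human-readable summary ---
  an_left <- contrasts[["adaptation_vs_neutral.left"]]
  an_right <- contrasts[["adaptation_vs_neutral.right"]]
  p2p_left_sig <- any(an_left$sig_mask[an_left$time_ms >= st$p2p_window[1] &
                                         an_left$time_ms < st$p2p_window[2]])
  p2p_right_sig <- any(an_right$sig_mask[an_right$time_ms >= st$p2p_window[1] &
                                           an_right$time_ms < st$p2p_window[2]])
  mean_underest <- mean(mag$percent)
  summary_lines <- c(
    sprintf("numadapt run %s (seed %d)", hash, config$seed),
    sprintf("behavioral underestimation: %.1f%% (Adaptation vs Neutral; %d/%d participants underestimated)",
            mean_underest, sum(mag$difference > 0), nrow(mag)),
    sprintf("one-way RM-ANOVA: F(%g,%g) = %.2f, p = %.3g, eta^2 = %.3f",
            aov1$df[1], aov1$df[2], aov1$F, aov1$p, aov1$eta_squared),
    sprintf("P2p (%g-%g ms) Adaptation %s Neutral: %s",
            st$p2p_window[1], st$p2p_window[2],
            if (mean(amp_a) < mean(amp_n)) "<" else ">=",
            if (p2p_left_sig && !p2p_right_sig)
              "significant, left cluster only"
            else if (p2p_left_sig && p2p_right_sig)
              "significant in both clusters"
            else if (!p2p_left_sig && p2p_right_sig)
              "significant, right cluster only"
            else "not significant"),
    sprintf("brain-behavior Spearman rho = %.2f, p = %.3g", corr$rho, corr$p)
  )
  sum_path <- file.path(config$out_dir, "summary.txt")
  writeLines(summary_lines, sum_path)
  logf("%s", paste(summary_lines, collapse = "\n"))

  invisible(list(behavior = behavior_report, contrasts = contrasts,
                 correlation = corr,
                 paths = c(estimates = est_path, behavior = beh_path,
                           results = res_path, summary = sum_path, erp_paths)))
}
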