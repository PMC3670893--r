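#' Scenario presets
#'
#' Three canonical scenarios contrast the selective forces on sex
#' allocation:
#' * `"symmetric"` — equal embryonic proliferation and survival of male
#'   and female larvae (every survival context uses the female single-sex
#'   distribution) and mating before dispersal, a structure promoting
#'   Local Mate Competition.
#' * `"asymmetric_premating"` — females proliferate more than males and
#'   outcompete them in superparasitized hosts (the default survival
#'   distributions); mating occurs in the natal brood before dispersal.
#' * `"asymmetric_postmating"` — same developmental asymmetry, but wasps
#'   disperse first and mate in the population at large.
#'
#' All presets let wasps that did not mate in the natal brood mate after
#' dispersal, but each male fertilizes at most `virility` females
#' (default 1), so the mating market can be male-limited: under the
#' asymmetric presets soldier attrition of male clones leaves part of the
#' female population virgin, and virgins can only produce sons — the
#' feedback that drives the realized primary sex ratio above 0.5 and
#' raises it further with superparasitism.
#'
#' @return `scenario_presets()`: the preset names.
#' @export
scenario_presets <- function() {
  c("symmetric", "asymmetric_premating", "asymmetric_postmating")
}

#' @rdname scenario_presets
#' @param name Preset name, one of `scenario_presets()`.
#' @param base_config A [simulation_config()] to start from.
#' @param base_template A [strategy()] whose non-evolving fields are used
#'   where the preset does not override them; its `info_level` is forced
#'   to match `base_config`.
#' @return `scenario_config()`: a list with elements `config` and
#'   `template` (the strategy template with the preset's survival and
#'   mating overrides applied).
#' @examples
#' sc <- scenario_config("symmetric")
#' sc$template$survival$male_single_sex
#' @export
scenario_config <- function(name, base_config = simulation_config(),
                            base_template = NULL) {
  if (!name %in% scenario_presets()) {
    stop("unknown scenario '", name, "'; valid presets: ",
         paste(scenario_presets(), collapse = ", "), call. = FALSE)
  }
  validate_config(base_config)
  if (is.null(base_template)) {
    base_template <- strategy(info_level = base_config$info_level)
  }
  tpl <- base_template
  tpl$info_level <- base_config$info_level
  tpl$sex_choice <- strategy(0.5,
                             info_level = base_config$info_level)$sex_choice
  if (name == "symmetric") {
    fss <- survival_distributions()$female_single_sex
    tpl$survival <- survival_distributions(
      female_single_sex = fss, male_single_sex = fss,
      female_in_related_mixed = fss, male_in_related_mixed = fss,
      female_in_unrelated_mixed = fss, male_in_unrelated_mixed = fss
    )
    tpl$in_host_mating_ratio <- 1
  } else if (name == "asymmetric_premating") {
    tpl$survival <- survival_distributions()
    tpl$in_host_mating_ratio <- 1
  } else {
    tpl$survival <- survival_distributions()
    tpl$in_host_mating_ratio <- 0
  }
  tpl$dispersal_mating <- TRUE
  validate_strategy(tpl)
  list(config = base_config, template = tpl)
}

#' Default host-acceptance threshold grid
#'
#' Nine equally spaced thresholds spanning, under the default egg-count
#' influence of 0.3, host egg loads from 4 accepted eggs (rampant
#' superparasitism, beyond the default host limit of 3) down to single
#' parasitism.
#'
#' @return Numeric vector of nine thresholds.
#' @export
default_thresholds <- function() seq(0.05, 0.85, by = 0.1)

#' Sweep scenarios across host-acceptance thresholds
#'
#' For each threshold, runs [replicate_tournaments()] under the given
#' scenario preset and records the evolved allocation and realized sex
#' ratios of every replicate. Low thresholds admit already-parasitized
#' hosts and thus raise superparasitism; the reported `max_egg_load`
#' column is the egg load at which hosts stop being accepted, a direct
#' measure of the superparasitism level a threshold permits. Thresholds
#' at which the population cannot persist (extinction during a round, or
#' no viable starting strategies) are recorded with `stable = FALSE`
#' rather than raised as errors, mirroring the collapse of the extreme
#' superparasitism levels.
#'
#' @param preset A name from [scenario_presets()].
#' @param thresholds Host-acceptance thresholds to sweep.
#' @param replicates Tournament replicates per threshold.
#' @param base_seed Seed; each (threshold, replicate) cell derives its
#'   own seed via [derive_seed()].
#' @param base_config,base_template Passed to [scenario_config()].
#' @param ... Passed on to [tournament()] (`n_strategies`,
#'   `max_generations`, `screen_horizon`, ...).
#' @return A `"sweep_result"`: `results` (one row per threshold x
#'   replicate), `summary` (per-threshold means and SDs over stable
#'   replicates), and `preset`.
#' @export
threshold_sweep <- function(preset, thresholds = default_thresholds(),
                            replicates = 5L, base_seed = 1L,
                            base_config = simulation_config(),
                            base_template = NULL, ...) {
  if (!length(thresholds) || any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must be a non-empty vector of values in [0, 1]",
         call. = FALSE)
  }
  sc <- scenario_config(preset, base_config, base_template)
  rows <- list()
  for (ti in seq_along(thresholds)) {
    cfg <- sc$config
    cfg$host_acceptance_threshold <- thresholds[ti]
    load <- max_egg_load(thresholds[ti], sc$template$egg_count_influence)
    for (j in seq_len(replicates)) {
      seed <- derive_seed(base_seed, ti * 100003L + j)
      tr <- tryCatch(
        tournament(cfg, template = sc$template, seed = seed, ...),
        polywasp_extinction = function(e) NULL,
        polywasp_no_viable = function(e) NULL
      )
      rows[[length(rows) + 1L]] <- data.frame(
        preset = preset, threshold = thresholds[ti],
        max_egg_load = load, replicate = j, seed = seed,
        stable = !is.null(tr),
        alloc_empty = if (is.null(tr)) NA_real_ else tr$alloc_empty,
        primary = if (is.null(tr)) NA_real_ else tr$realized_primary,
        secondary = if (is.null(tr)) NA_real_ else tr$realized_secondary
      )
    }
  }
  results <- do.call(rbind, rows)
  sd0 <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  summ <- do.call(rbind, lapply(split(results, results$threshold), function(d) {
    s <- d[d$stable, , drop = FALSE]
    data.frame(
      preset = d$preset[1], threshold = d$threshold[1],
      max_egg_load = d$max_egg_load[1],
      n_stable = nrow(s), n_replicates = nrow(d),
      alloc_empty_mean = if (nrow(s)) mean(s$alloc_empty) else NA_real_,
      alloc_empty_sd = if (nrow(s)) sd0(s$alloc_empty) else NA_real_,
      primary_mean = if (nrow(s)) mean(s$primary) else NA_real_,
      primary_sd = if (nrow(s)) sd0(s$primary) else NA_real_,
      secondary_mean = if (nrow(s)) mean(s$secondary) else NA_real_,
      secondary_sd = if (nrow(s)) sd0(s$secondary) else NA_real_
    )
  }))
  summ <- summ[order(summ$threshold), ]
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, preset = preset),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> preset:", x$preset, "\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Plot a threshold sweep
#'
#' Evolved primary (top panel) and realized secondary (bottom panel) sex
#' ratios against the host-acceptance threshold, with the 1:1 allocation
#' marked by a dashed line. Requires ggplot2.
#'
#' @param x A `"sweep_result"` (or several, to overlay presets).
#' @return A ggplot object.
#' @export
plot_sweep <- function(x) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sweep() requires the ggplot2 package", call. = FALSE)
  }
  if (inherits(x, "sweep_result")) x <- list(x)
  summ <- do.call(rbind, lapply(x, function(s) s$summary))
  long <- rbind(
    data.frame(summ[c("preset", "threshold")], panel = "primary",
               mean = summ$primary_mean, sd = summ$primary_sd),
    data.frame(summ[c("preset", "threshold")], panel = "secondary",
               mean = summ$secondary_mean, sd = summ$secondary_sd)
  )
  long <- long[!is.na(long$mean), ]
  ggplot2::ggplot(long, ggplot2::aes(
    x = threshold, y = mean, colour = preset, shape = preset)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean - sd,
                                          ymax = mean + sd)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1) +
    ggplot2::labs(x = "host acceptance threshold (low = superparasitism)",
                  y = "sex ratio (proportion male)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
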