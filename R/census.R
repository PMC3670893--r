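#' Brood census
#'
#' Aggregated counts from a brood-rearing experiment: how many broods
#' (all wasps emerging from one host) were all-male, all-female or
#' mixed-sex, and how many adult wasps emerged from each brood class.
#' Optionally carries the per-brood records it was aggregated from.
#'
#' @param n_male_broods,n_female_broods,n_mixed_broods Brood counts.
#' @param wasps_in_male_broods,wasps_in_female_broods,
#'   wasps_in_mixed_broods Total adult wasps per brood class.
#' @param broods Optional per-brood data frame (see
#'   [generate_brood_census()]).
#' @return An object of class `"brood_census"`.
#' @examples
#' brood_census(13, 13, 14, 420, 590, 630)
#' @export
brood_census <- function(n_male_broods, n_female_broods, n_mixed_broods,
                         wasps_in_male_broods = 0L,
                         wasps_in_female_broods = 0L,
                         wasps_in_mixed_broods = 0L,
                         broods = NULL) {
  x <- structure(list(
    n_male_broods = as.integer(n_male_broods),
    n_female_broods = as.integer(n_female_broods),
    n_mixed_broods = as.integer(n_mixed_broods),
    wasps_in_male_broods = as.integer(wasps_in_male_broods),
    wasps_in_female_broods = as.integer(wasps_in_female_broods),
    wasps_in_mixed_broods = as.integer(wasps_in_mixed_broods),
    broods = broods
  ), class = "brood_census")
  cnt <- unlist(x[1:6])
  if (any(is.na(cnt)) || any(cnt < 0)) {
    stop("all census counts must be non-negative", call. = FALSE)
  }
  for (cls in c("male", "female", "mixed")) {
    nb <- x[[paste0("n_", cls, "_broods")]]
    nw <- x[[paste0("wasps_in_", cls, "_broods")]]
    if (nb > 0L && nw > 0L && nw < nb) {
      stop("wasps_in_", cls, "_broods must be at least the number of ",
           cls, " broods", call. = FALSE)
    }
  }
  x
}

#' @export
print.brood_census <- function(x, ...) {
  cat("<brood_census>\n")
  cat(sprintf("  broods: %d all-male, %d all-female, %d mixed-sex\n",
              x$n_male_broods, x$n_female_broods, x$n_mixed_broods))
  cat(sprintf("  wasps:  %d, %d, %d\n", x$wasps_in_male_broods,
              x$wasps_in_female_broods, x$wasps_in_mixed_broods))
  invisible(x)
}

total_broods <- function(census) {
  census$n_male_broods + census$n_female_broods + census$n_mixed_broods
}

#' Proportion of mixed-sex broods
#'
#' The fraction of broods containing both sexes. Because a mixed-sex
#' brood requires a host parasitized by at least two eggs, this
#' proportion serves as a field estimate of the frequency of
#' superparasitized hosts.
#'
#' @param census A [brood_census()].
#' @return Proportion in `[0, 1]`.
#' @examples
#' mixed_brood_proportion(brood_census(13, 13, 14))
#' @export
mixed_brood_proportion <- function(census) {
  tot <- total_broods(census)
  if (tot == 0) stop("census contains no broods", call. = FALSE)
  census$n_mixed_broods / tot
}

#' Estimate the primary sex ratio from a brood census
#'
#' Eggs are not observable in the field, so the proportion of male eggs
#' laid (the primary sex ratio, the operational measure of sex
#' allocation) is reconstructed from brood sex compositions under the
#' superparasitism assumption: a fraction `p_super` of the single-sex
#' broods arose from two eggs of the same sex, and every mixed-sex brood
#' from exactly one male and one female egg. Under the default
#' expectation form each single-sex brood then represents `1 + p_super`
#' eggs on average, giving
#'
#' \deqn{\hat r = \frac{(1+p)\,n_{male} + n_{mixed}}
#'                     {(1+p)(n_{male}+n_{female}) + 2\,n_{mixed}}.}
#'
#' `method = "integer"` instead allocates exactly
#' `ceiling(p_super * n)` double-egg broods to each single-sex class.
#'
#' @param census A [brood_census()].
#' @param p_super Assumed fraction of single-sex broods that received two
#'   eggs; conventionally set to the observed [mixed_brood_proportion()].
#' @param method `"expectation"` (default) or `"integer"`.
#' @return Estimated proportion of male eggs, in `[0, 1]`.
#' @examples
#' estimate_primary_sex_ratio(brood_census(50, 30, 20), p_super = 0.35)
#' @export
estimate_primary_sex_ratio <- function(census, p_super = 0.35,
                                       method = c("expectation", "integer")) {
  method <- match.arg(method)
  if (p_super < 0 || p_super > 1) {
    stop("p_super must lie in [0, 1]", call. = FALSE)
  }
  if (total_broods(census) == 0) {
    stop("census contains no broods", call. = FALSE)
  }
  nm <- census$n_male_broods
  nf <- census$n_female_broods
  nx <- census$n_mixed_broods
  if (method == "expectation") {
    male_eggs <- (1 + p_super) * nm + nx
    total_eggs <- (1 + p_super) * (nm + nf) + 2 * nx
  } else {
    male_eggs <- nm + ceiling(p_super * nm) + nx
    total_eggs <- male_eggs + nf + ceiling(p_super * nf) + nx
  }
  male_eggs / total_eggs
}

#' Estimate the secondary sex ratio from a brood census
#'
#' The proportion of males among emerging adults, computed as
#' `(wasps in all-male broods + male_frac_mixed * wasps in mixed broods)
#' / total wasps`. The default `male_frac_mixed = 1/3` reflects the
#' observation that males comprise about one third of mixed-sex broods.
#'
#' @param census A [brood_census()].
#' @param male_frac_mixed Assumed male fraction within mixed-sex broods.
#' @return Estimated proportion of adult males, in `[0, 1]`.
#' @examples
#' estimate_secondary_sex_ratio(brood_census(3, 3, 3, 300, 300, 300))
#' @export
estimate_secondary_sex_ratio <- function(census, male_frac_mixed = 1 / 3) {
  tot <- census$wasps_in_male_broods + census$wasps_in_female_broods +
    census$wasps_in_mixed_broods
  if (tot == 0) stop("census contains no wasps", call. = FALSE)
  (census$wasps_in_male_broods +
      male_frac_mixed * census$wasps_in_mixed_broods) / tot
}

#' Generate a synthetic brood census
#'
#' Stand-in for a laboratory brood-rearing dataset, emulating only the
#' statistical structure the census estimators assume: each host receives
#' two eggs with probability `p_host_double_egg` (else one); each egg is
#' male with probability `true_primary_ratio`; each egg's emergence count
#' is drawn from the survival distribution of its context (single-sex for
#' sole or same-sex eggs, the unrelated mixed-sex contexts for two-sex
#' hosts, where soldiers depress male emergence). There is no evolution
#' and no within-host egg-count feedback. Hosts from which no adult
#' emerges are dropped, as they would be in a reared sample.
#'
#' @param true_primary_ratio Probability an egg is male.
#' @param p_host_double_egg Probability a host receives a second egg.
#' @param n_hosts Number of hosts reared.
#' @param survival A [survival_distributions()].
#' @return A [brood_census()] whose `broods` element records, per host,
#'   the egg count, male egg count, emerging males/females and the brood
#'   class.
#' @examples
#' set.seed(1)
#' cen <- generate_brood_census(0.6, 0.35, 1000)
#' mixed_brood_proportion(cen)
#' @export
generate_brood_census <- function(true_primary_ratio, p_host_double_egg,
                                  n_hosts,
                                  survival = survival_distributions()) {
  stopifnot(true_primary_ratio >= 0, true_primary_ratio <= 1,
            p_host_double_egg >= 0, p_host_double_egg <= 1, n_hosts >= 1)
  n_eggs <- 1L + stats::rbinom(n_hosts, 1L, p_host_double_egg)
  egg1_male <- stats::runif(n_hosts) < true_primary_ratio
  egg2_male <- stats::runif(n_hosts) < true_primary_ratio
  egg2_male[n_eggs == 1L] <- NA
  mixed <- n_eggs == 2L & (egg1_male != egg2_male)

  draw <- function(sel, ctx) {
    out <- integer(length(sel))
    if (any(sel)) out[sel] <- sample_clone_size(sum(sel), survival[[ctx]])
    out
  }
  m1 <- draw(egg1_male & !mixed, "male_single_sex") +
    draw(egg1_male & mixed, "male_in_unrelated_mixed")
  f1 <- draw(!egg1_male & !mixed, "female_single_sex") +
    draw(!egg1_male & mixed, "female_in_unrelated_mixed")
  has2 <- n_eggs == 2L
  m2 <- draw(has2 & egg2_male %in% TRUE & !mixed, "male_single_sex") +
    draw(has2 & egg2_male %in% TRUE & mixed, "male_in_unrelated_mixed")
  f2 <- draw(has2 & egg2_male %in% FALSE & !mixed, "female_single_sex") +
    draw(has2 & egg2_male %in% FALSE & mixed, "female_in_unrelated_mixed")

  males <- m1 + m2
  females <- f1 + f2
  emerged <- males + females > 0L
  cls <- ifelse(males > 0L & females > 0L, "mixed",
                ifelse(males > 0L, "male", "female"))
  cls[!emerged] <- NA
  broods <- data.frame(
    host = seq_len(n_hosts), n_eggs = n_eggs,
    eggs_male = as.integer(egg1_male) +
      ifelse(is.na(egg2_male), 0L, as.integer(egg2_male)),
    males = males, females = females, class = cls
  )
  kept <- broods[emerged, , drop = FALSE]
  brood_census(
    n_male_broods = sum(kept$class == "male"),
    n_female_broods = sum(kept$class == "female"),
    n_mixed_broods = sum(kept$class == "mixed"),
    wasps_in_male_broods = sum(kept$males[kept$class == "male"]),
    wasps_in_female_broods = sum(kept$females[kept$class == "female"]),
    wasps_in_mixed_broods = sum(kept$males[kept$class == "mixed"] +
                                  kept$females[kept$class == "mixed"]),
    broods = broods
  )
}

#' Realized double-egg fraction among single-sex broods
#'
#' From the per-brood records of a generated census: the fraction of
#' broods classified single-sex (by emergence) that actually developed
#' from two eggs. Plugging this into
#' [estimate_primary_sex_ratio()]'s `p_super` closes the
#' generator-to-estimator loop for parameter-recovery checks.
#'
#' @param census A [brood_census()] carrying per-brood records.
#' @return Fraction in `[0, 1]`.
#' @export
single_sex_double_fraction <- function(census) {
  b <- census$broods
  if (is.null(b)) {
    stop("census carries no per-brood records", call. = FALSE)
  }
  ss <- b[!is.na(b$class) & b$class %in% c("male", "female"), , drop = FALSE]
  if (!nrow(ss)) stop("census has no single-sex broods", call. = FALSE)
  mean(ss$n_eggs == 2L)
}

#' Arcsine-square-root transform
#'
#' Variance-stabilizing transform conventionally applied to proportions
#' before ANOVA: `asin(sqrt(p))`.
#'
#' @param p Proportions in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]`.
#' @export
asin_sqrt <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  asin(sqrt(p))
}
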