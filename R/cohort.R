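## Synthetic observer cohorts: the statistical stand-in for the study's
## subjects. Cohorts are generated either directly in threshold units
## (per-montage uA distributions) or coupled to the forward model (one
## retinal-density threshold per subject, divided by each montage's
## simulated retinal coupling).

#' Cohort specification
#'
#' @param n number of subjects (default 15, the study cohort size).
#' @param mode `"direct"`: per-montage thresholds drawn from
#'   `Normal(mean_uA, sd_uA)` truncated to `trunc_uA`; `"coupled"`: one
#'   retinal current-density threshold per subject drawn from
#'   `Normal(density_mean, density_sd)` (mA/m^2) truncated to
#'   `density_trunc`, converted per montage via the coupling table.
#' @param mean_uA,sd_uA threshold distribution (uA); either scalars or
#'   named per-montage vectors. Defaults 95 and 33 (the F7-F8 values).
#' @param trunc_uA truncation bounds (uA) keeping true thresholds inside
#'   the protocol's dynamic range.
#' @param density_mean,density_sd,density_trunc retinal-density threshold
#'   distribution (mA/m^2) for coupled mode. The default mean 3.7 mA/m^2 is
#'   the F7-F8 eye-model coupling (38.5 mA/m^2 per mA) times the reported
#'   95 uA mean threshold.
#' @param slope_uA,lapse,fp,gate5 psychometric parameters passed to every
#'   [observer_model()].
#' @param dominance_effect_uA additive threshold shift for left-dominant
#'   subjects (default 0: eye dominance is generated as a label with no
#'   effect).
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 15, mode = c("direct", "coupled"),
                        mean_uA = 95, sd_uA = 33, trunc_uA = c(30, 450),
                        density_mean = 3.7, density_sd = 1.2,
                        density_trunc = c(0.5, 12),
                        slope_uA = 0, lapse = 0, fp = 0, gate5 = 0,
                        dominance_effect_uA = 0) {
  mode <- match.arg(mode)
  if (n < 1) stop("n must be >= 1")
  if (any(sd_uA < 0) || density_sd < 0) stop("SDs must be >= 0")
  if (trunc_uA[1] >= trunc_uA[2] || density_trunc[1] >= density_trunc[2])
    stop("truncation bounds are inverted")
  structure(list(n = as.integer(n), mode = mode, mean_uA = mean_uA,
                 sd_uA = sd_uA, trunc_uA = trunc_uA,
                 density_mean = density_mean, density_sd = density_sd,
                 density_trunc = density_trunc, slope_uA = slope_uA,
                 lapse = lapse, fp = fp, gate5 = gate5,
                 dominance_effect_uA = dominance_effect_uA),
            class = "cohort_spec")
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(hi, pmax(lo, mean)), n))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic observer cohort
#'
#' @param spec a [cohort_spec()].
#' @param montages montage names; in direct mode per-montage `mean_uA` /
#'   `sd_uA` entries are matched by name (scalars are recycled).
#' @param coupling named numeric vector `montage -> c_m` (mA/m^2 of mean
#'   retinal current density per mA injected), required in coupled mode;
#'   thresholds are `theta_m = 1000 * density_threshold / c_m` uA, so
#'   montages with higher simulated retinal density get lower thresholds by
#'   construction.
#' @param seed RNG seed (master seed of the cohort).
#' @return object of class `observer_cohort`: list with `theta` (n x
#'   montages matrix, uA), `dominance`, `spec`, `montages`, and the
#'   per-subject observer parameters.
#' @export
generate_cohort <- function(spec, montages = "F7-F8", coupling = NULL,
                            seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  m <- length(montages)
  theta <- matrix(NA_real_, spec$n, m, dimnames = list(NULL, montages))
  if (spec$mode == "direct") {
    mu <- rep(spec$mean_uA, length.out = m)
    sdv <- rep(spec$sd_uA, length.out = m)
    if (!is.null(names(spec$mean_uA))) mu <- spec$mean_uA[montages]
    if (!is.null(names(spec$sd_uA))) sdv <- spec$sd_uA[montages]
    for (j in seq_len(m))
      theta[, j] <- rtruncnorm(spec$n, mu[j], sdv[j],
                               spec$trunc_uA[1], spec$trunc_uA[2])
  } else {
    if (is.null(coupling)) stop("coupled mode needs a coupling table")
    c_m <- coupling[montages]
    if (any(is.na(c_m)) || any(c_m <= 0))
      stop("coupling must be positive for every montage")
    dens <- rtruncnorm(spec$n, spec$density_mean, spec$density_sd,
                       spec$density_trunc[1], spec$density_trunc[2])
    theta <- 1000 * outer(dens, 1 / c_m)
    dimnames(theta) <- list(NULL, montages)
  }
  dominance <- sample(c("right", "left"), spec$n, replace = TRUE)
  theta <- theta + ifelse(dominance == "left", spec$dominance_effect_uA, 0)
  structure(list(theta = theta, dominance = dominance, montages = montages,
                 spec = spec, seed = seed),
            class = "observer_cohort")
}

## derived per-subject RNG stream seed, kept below 2^31
subject_seed <- function(master, i) {
  (as.numeric(master) * 48271 + i * 30269) %% 2147483647
}

#' Simulate a full threshold study
#'
#' Runs the three-step protocol once per subject and montage, with the
#' montage order randomized per subject (as in the study design) and one
#' reproducible RNG stream per subject derived from the master seed.
#'
#' @param cohort an [generate_cohort()] result.
#' @param seed master seed for the measurement phase.
#' @param keep_logs keep the per-trial logs (memory-heavy for large runs).
#' @return list of class `study_result`: `pt` (n x montages matrix, uA; NA
#'   where the protocol found no threshold), `valid`, `order` (montage
#'   presentation order per subject), optionally `logs`.
#' @export
simulate_study <- function(cohort, seed = 1L, keep_logs = FALSE) {
  stopifnot(inherits(cohort, "observer_cohort"))
  mts <- cohort$montages
  n <- nrow(cohort$theta)
  pt <- matrix(NA_real_, n, length(mts), dimnames = list(NULL, mts))
  valid <- matrix(FALSE, n, length(mts), dimnames = list(NULL, mts))
  ord <- matrix(NA_integer_, n, length(mts))
  logs <- if (keep_logs) vector("list", n) else NULL
  sp <- cohort$spec
  for (i in seq_len(n)) {
    set.seed(subject_seed(seed, i))
    oi <- sample.int(length(mts))
    ord[i, ] <- oi
    if (keep_logs) logs[[i]] <- list()
    for (j in oi) {
      obs <- observer_model(cohort$theta[i, j], sp$slope_uA, sp$lapse,
                            sp$fp, sp$gate5)
      rec <- run_protocol(obs, subject = i, montage = mts[j])
      pt[i, j] <- rec$pt
      valid[i, j] <- rec$valid
      if (keep_logs) logs[[i]][[mts[j]]] <- rec$trials
    }
  }
  structure(list(pt = pt, valid = valid, order = ord, logs = logs,
                 seed = seed), class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", nrow(x$pt), "subjects x", ncol(x$pt), "montages\n")
  print(apply(x$pt, 2, stats::median, na.rm = TRUE))
  invisible(x)
}

#' Load the packaged reference tables
#'
#' Reads the transcribed threshold/current-density tables shipped with the
#' package (`inst/extdata`): the PT and right-eye density table, the
#' visual-pathway (LGN / occipital cortex) table, and the five unilateral
#' eye-model densities from the regression-figure caption. A checksum over
#' the numeric content guards against transcription drift.
#'
#' @return list of class `fixture_tables` with data.frames `table1`,
#'   `table2`, `fig4`.
#' @export
load_fixtures <- function() {
  path <- function(f) system.file("extdata", f, package = "phosfem",
                                  mustWork = TRUE)
  t1 <- utils::read.csv(path("table1_pt_eye_density.csv"), comment.char = "#")
  t2 <- utils::read.csv(path("table2_visual_pathway.csv"), comment.char = "#")
  f4 <- utils::read.csv(path("fig4_eye_densities.csv"), comment.char = "#")
  sums <- c(sum(as.matrix(t1[-1])), sum(as.matrix(t2[-1])),
            sum(f4$eye_density_eye_model))
  expected <- c(3855.2, 1574.3, 582.5)
  if (any(abs(sums - expected) > 1e-6))
    stop("fixture tables are corrupted (checksum mismatch)")
  structure(list(table1 = t1, table2 = t2, fig4 = f4),
            class = "fixture_tables")
}

#' Calibrate the coupled-mode density threshold to a phantom
#'
#' Anchors the retinal-density threshold distribution to the reported F7-F8
#' threshold scale (mean 95 uA, SD 33 uA) through the phantom's own
#' simulated coupling: `density = PT * c_m / 1000`. This keeps coupled-mode
#' cohorts inside the protocol's dynamic range for any phantom resolution.
#'
#' @param coupling named coupling vector (mA/m^2 per mA) from the forward
#'   model.
#' @param montage anchor montage (default `"F7-F8"`).
#' @param mean_pt_uA,sd_pt_uA anchor threshold distribution (uA).
#' @return named vector `c(density_mean =, density_sd =)` in mA/m^2.
#' @export
calibrate_density_threshold <- function(coupling, montage = "F7-F8",
                                        mean_pt_uA = 95, sd_pt_uA = 33) {
  c_m <- coupling[montage]
  if (is.na(c_m) || c_m <= 0) stop("no positive coupling for ", montage)
  c(density_mean = unname(mean_pt_uA * c_m / 1000),
    density_sd = unname(sd_pt_uA * c_m / 1000))
}
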