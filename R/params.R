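#' @title Model parameter sets
#' @description
#' A parameter set (`mt_params`) bundles every quantity of the decision
#' model: cohort composition, radiographic (Kellgren-Lawrence) progression,
#' OA incidence and total knee arthroplasty (TKA) uptake by age, health-state
#' utilities, quarterly pain-transition probabilities for the three treatment
#' contexts (APM, APM after failed PT, PT) by KL band, OA-driven annual pain
#' dynamics, TKA efficacy, adverse events, direct medical costs, productivity
#' hours, the employment schedule, the discount rate and the horizon.
#' Uncertain entries are [dist_beta()] / [dist_gamma()] specifications;
#' everything else is fixed.
#' @name mt_params
NULL

# canonical leaf paths holding a distribution spec, in sampling order
.dist_paths <- local({
  ctx <- c("APM", "APM_after_PT", "PT")
  band <- c("kl02", "kl34")
  tp <- unlist(lapply(c("failed_relief", "incidence_q2", "resolution_q2"),
                      function(op) unlist(lapply(ctx, function(cx)
                        paste("treatment_pain", op, cx, band, sep = ".")))))
  c(tp,
    paste("costs", c("apm_procedure", "apm_healthcare", "apm_rehab",
                     "pt_healthcare", "pt_rehab", "pain_mgmt_moderate",
                     "pain_mgmt_low", "tka_procedure"), sep = "."),
    paste("time_costs", c("hours_q1_apm", "hours_q1_pt", "hours_q2_moderate",
                          "hours_q2_low", "hours_later_moderate",
                          "hours_later_low"), sep = "."))
})

get_path <- function(x, path) {
  for (k in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    if (is.null(x <- x[[k]]))
      return(NULL)
  }
  x
}

set_path <- function(x, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  if (length(keys) == 1L) {
    x[[keys]] <- value
    return(x)
  }
  x[[keys[1L]]] <- set_path(x[[keys[1L]]], paste(keys[-1L], collapse = "."), value)
  x
}

parse_dist_node <- function(node, key) {
  if (inherits(node, "mt_dist")) return(node)
  if (is.numeric(node) && length(node) == 1L) return(dist_fixed(node))
  if (is.list(node) && !is.null(node$dist)) {
    out <- switch(as.character(node$dist),
      beta  = dist_beta(node$alpha, node$beta),
      gamma = dist_gamma(node$alpha, node$lambda, mean = node$mean),
      fixed = dist_fixed(node$mean),
      stop(sprintf("parameter '%s': unknown distribution family '%s'",
                   key, node$dist), call. = FALSE))
    return(out)
  }
  stop(sprintf("parameter '%s': malformed distribution entry", key),
       call. = FALSE)
}

#' Load a model parameter set from a YAML configuration file
#'
#' The packaged default configuration encodes the published base-case
#' parameter table in full; any field can be overridden by editing a copy.
#'
#' @param config_path Path to a YAML file. Defaults to the packaged
#'   configuration.
#' @return A validated object of class `mt_params`.
#' @examples
#' ps <- load_parameters()
#' ps$utilities$low_pain
#' @export
load_parameters <- function(config_path = default_config_path()) {
  if (!file.exists(config_path))
    stop(sprintf("config file not found: %s", config_path), call. = FALSE)
  raw <- tryCatch(yaml::read_yaml(config_path),
                  error = function(e) stop(sprintf(
                    "malformed config file '%s': %s", config_path,
                    conditionMessage(e)), call. = FALSE))
  ps <- as_mt_params(raw)
  attr(ps, "config_path") <- config_path
  ps
}

#' @rdname load_parameters
#' @export
default_config_path <- function() {
  system.file("extdata", "default_params.yaml", package = "mtcea",
              mustWork = TRUE)
}

#' @rdname load_parameters
#' @param x A list with the structure of the YAML configuration.
#' @export
as_mt_params <- function(x) {
  required <- c("cohort", "kl_progression", "oa_incidence_by_age",
                "tka_uptake_by_age", "utilities", "treatment_pain", "oa_pain",
                "tka_efficacy", "adverse_events", "costs", "time_costs",
                "employment", "discount_rate_annual", "horizon_years")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(sprintf("missing parameter section(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (p in .dist_paths) {
    node <- get_path(x, p)
    if (is.null(node))
      stop(sprintf("missing parameter '%s'", p), call. = FALSE)
    x <- set_path(x, p, parse_dist_node(node, p))
  }
  x$cohort$kl_shares <- as.numeric(unlist(x$cohort$kl_shares))
  ps <- structure(x, class = "mt_params")
  validate_parameters(ps)
  ps
}

#' Convenience constructor for the packaged default parameter set
#'
#' @return A validated `mt_params` object holding the base-case point
#'   estimates and PSA distributions.
#' @export
default_parameters <- function() load_parameters()

#' Validate a parameter set
#'
#' Checks every structural invariant: probabilities in `[0, 1]`, KL shares
#' summing to one, non-negative costs and hours, and well-formed
#' distribution specifications. Called on construction and after PSA
#' sampling; errors name the offending key.
#'
#' @param ps An `mt_params` object.
#' @return `ps`, invisibly, if valid; otherwise an error.
#' @export
validate_parameters <- function(ps) {
  fail <- function(key, msg)
    stop(sprintf("invalid parameter '%s': %s", key, msg), call. = FALSE)
  chk_prob <- function(v, key) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0) || any(v > 1))
      fail(key, "must be a probability in [0, 1]")
  }
  chk_pos <- function(v, key, strict = FALSE) {
    if (!is.numeric(v) || any(!is.finite(v)) || any(if (strict) v <= 0 else v < 0))
      fail(key, if (strict) "must be positive" else "must be non-negative")
  }

  ks <- ps$cohort$kl_shares
  if (length(ks) != 4L) fail("cohort.kl_shares", "must have 4 entries")
  chk_prob(ks, "cohort.kl_shares")
  if (abs(sum(ks) - 1) > 1e-9)
    fail("cohort.kl_shares", sprintf("must sum to 1 (got %.6f)", sum(ks)))
  chk_pos(ps$cohort$age_sd, "cohort.age_sd")
  if (ps$cohort$age_min >= ps$cohort$age_max)
    fail("cohort.age_min", "must be below cohort.age_max")

  chk_prob(ps$kl_progression$kl2_to_kl3, "kl_progression.kl2_to_kl3")
  chk_prob(ps$kl_progression$kl3_to_kl4, "kl_progression.kl3_to_kl4")
  for (sec in c("oa_incidence_by_age", "tka_uptake_by_age")) {
    b <- ps[[sec]]$breaks; v <- ps[[sec]]$values
    if (length(b) != length(v)) fail(sec, "breaks and values lengths differ")
    if (is.unsorted(b, strictly = TRUE)) fail(sec, "breaks must increase")
    chk_prob(v, sec)
  }
  chk_prob(unlist(ps$utilities), "utilities")
  chk_prob(unlist(ps$oa_pain), "oa_pain")
  chk_prob(unlist(ps$tka_efficacy), "tka_efficacy")
  for (tr in names(ps$adverse_events)) {
    ae <- ps$adverse_events[[tr]]
    chk_prob(ae[[1L]], paste0("adverse_events.", tr))
    chk_prob(ae$mortality, paste0("adverse_events.", tr, ".mortality"))
    chk_pos(ae$cost, paste0("adverse_events.", tr, ".cost"))
  }
  for (p in .dist_paths) {
    spec <- get_path(ps, p)
    if (!inherits(spec, "mt_dist")) fail(p, "must be a distribution spec")
    if (spec$family != "fixed" && (spec$a <= 0 || spec$b <= 0))
      fail(p, "shape/rate must be positive")
    if (startsWith(p, "treatment_pain")) chk_prob(spec$mean, p)
    else chk_pos(spec$mean, p)
  }
  chk_pos(ps$time_costs$wage, "time_costs.wage")
  emp <- ps$employment
  chk_prob(emp$baseline, "employment.baseline")
  chk_prob(emp$floor_value, "employment.floor_value")
  if (emp$floor_age <= emp$decline_start_age)
    fail("employment.floor_age", "must exceed employment.decline_start_age")
  if (!is.numeric(ps$discount_rate_annual) || ps$discount_rate_annual < 0)
    fail("discount_rate_annual", "must be non-negative")
  chk_pos(ps$horizon_years, "horizon_years")
  invisible(ps)
}

#' @export
print.mt_params <- function(x, ...) {
  sampled <- sum(vapply(.dist_paths, function(p) is_sampled(get_path(x, p)),
                        logical(1L)))
  cat("<mt_params>\n")
  cat(sprintf("  cohort: mean age %g (SD %g), KL shares %s\n",
              x$cohort$age_mean, x$cohort$age_sd,
              paste(format(x$cohort$kl_shares), collapse = "/")))
  cat(sprintf("  horizon %g y, quarterly cycles, discount %.1f%%/y\n",
              x$horizon_years, 100 * x$discount_rate_annual))
  cat(sprintf("  %d of %d distribution entries sampled in PSA\n",
              sampled, length(.dist_paths)))
  invisible(x)
}

#' Deterministic child seed for a PSA iteration
#'
#' One master seed governs a whole analysis; each PSA iteration uses a
#' deterministic child so that any single iteration can be replayed in
#' isolation with [sample_psa()].
#'
#' @param master Master seed (integer).
#' @param i Iteration index (1-based).
#' @return An integer seed below 2^31.
#' @export
child_seed <- function(master, i) {
  as.integer((as.numeric(master) + 1000003 * as.numeric(i)) %% 2147483647)
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Every entry carrying a beta or gamma specification is replaced by an
#' independent random draw (stored as a fixed spec, so the draw becomes the
#' point estimate used by the engine); all fixed entries are untouched. All
#' draws are independent: no correlation structure is imposed.
#'
#' @param ps An `mt_params` object.
#' @param seed Integer seed; the same seed reproduces the same draw.
#' @return A validated `mt_params` object with `attr(, "psa_draw") = TRUE`.
#' @export
sample_psa <- function(ps, seed) {
  stopifnot(inherits(ps, "mt_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  for (p in .dist_paths) {
    spec <- get_path(ps, p)
    if (is_sampled(spec))
      ps <- set_path(ps, p, dist_fixed(draw_dist(spec)))
  }
  validate_parameters(ps)
  attr(ps, "psa_draw") <- TRUE
  ps
}

#' Names of the PSA-sampled parameter leaves of a parameter set
#'
#' @param ps An `mt_params` object.
#' @return Character vector of dotted paths (in canonical sampling order).
#' @export
psa_sampled_paths <- function(ps) {
  .dist_paths[vapply(.dist_paths, function(p) is_sampled(get_path(ps, p)),
                     logical(1L))]
}
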