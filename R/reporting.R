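#' Run a configured analysis and write its artifact files
#'
#' Executes one of the packaged analyses and writes plot-ready CSV/JSON
#' outputs plus a run manifest (seeds, package version, config hash) to an
#' output directory. Available analyses:
#' \describe{
#'   \item{`base-case`}{deterministic cohort run of all strategies; writes
#'     `cea_table.csv` (cost/QALY/ICER rows) and `trajectories.csv`
#'     (per-quarter moderate-pain and cumulative-TKA fractions).}
#'   \item{`psa`}{probabilistic sensitivity analysis; writes
#'     `psa_draws.csv` and `cea_table.csv` of PSA means.}
#'   \item{`ceac`}{PSA plus `ceac.csv` and `ceaf.csv` over the WTP grid.}
#'   \item{`voi`}{PSA plus `voi.json` (EVPI by WTP, EVPPI by group,
#'     population VOI).}
#'   \item{`sensitivity`}{deterministic scenario table (`sensitivity.csv`):
#'     time costs, delayed-efficacy scenario, progression multipliers.}
#' }
#'
#' @param config A list (or YAML file path) with elements `analysis`, and
#'   optionally `params` (parameter config path), `life_table` (CSV path),
#'   `out_dir`, `seed`, `iterations`, `wtp_grid` (`c(from, to, by)`),
#'   `wtp` (VOI threshold), `include_time_costs`, `horizon_years`,
#'   `delayed_efficacy`, `progression_multipliers`, `evppi_groups`,
#'   `evppi_outer_n`, `evppi_inner_n`.
#' @return Invisibly, the list of files written. Partial outputs are removed
#'   on error.
#' @export
cmd_run <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  analysis <- match.arg(config$analysis,
                        c("base-case", "psa", "ceac", "voi", "sensitivity"))
  out_dir <- config$out_dir %||% "mtcea_output"
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  iterations <- as.integer(config$iterations %||% 1000L)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  params_path <- config$params %||% default_config_path()
  ps <- load_parameters(params_path)
  if (!is.null(config$horizon_years))
    ps$horizon_years <- as.numeric(config$horizon_years)
  lt <- if (is.null(config$life_table)) load_life_table()
        else load_life_table(config$life_table)
  wtp_grid <- if (is.null(config$wtp_grid)) wtp_grid_default()
              else seq(config$wtp_grid[1L], config$wtp_grid[2L],
                       by = config$wtp_grid[3L])
  opts <- list(include_time_costs = isTRUE(config$include_time_costs),
               delayed_efficacy = config$delayed_efficacy %||% "crossover",
               apm_progression_multiplier =
                 config$progression_multiplier %||% 1,
               life_table = lt)

  written <- character(0)
  on.exit(if (!is.null(attr(written, "failed")))
    unlink(written), add = TRUE)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    written <<- c(written, path)
    path
  }
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  base_tables <- function() {
    tab <- run_all_strategies(ps, opts)
    cea <- icer_table(tab[, c("strategy", "cost", "qalys")])
    list(tab = tab, cea = merge(tab, as.data.frame(
      cea[, c("strategy", "status", "icer")]), by = "strategy", sort = FALSE))
  }

  if (analysis == "base-case") {
    bt <- base_tables()
    emit("cea_table.csv", function(p) utils::write.csv(bt$cea, p, row.names = FALSE))
    trows <- lapply(strategies(), function(s) {
      r <- run_strategy(s, ps, opts)
      cbind(strategy = s, r$trajectory)
    })
    emit("trajectories.csv", function(p)
      utils::write.csv(do.call(rbind, trows), p, row.names = FALSE))
  } else if (analysis == "sensitivity") {
    scen <- list(
      list(name = "base_case", o = list()),
      list(name = "time_costs", o = list(include_time_costs = TRUE)),
      list(name = "delayed_equals_immediate",
           o = list(delayed_efficacy = "same_as_immediate")),
      list(name = "delayed_equals_immediate_time_costs",
           o = list(delayed_efficacy = "same_as_immediate",
                    include_time_costs = TRUE)))
    for (m in config$progression_multipliers %||% numeric(0))
      scen <- c(scen, list(list(name = sprintf("progression_x%g", m),
                                o = list(apm_progression_multiplier = m))))
    rows <- lapply(scen, function(sc) {
      o <- utils::modifyList(opts, sc$o)
      tab <- run_all_strategies(ps, o)
      cea <- icer_table(tab[, c("strategy", "cost", "qalys")])
      cbind(scenario = sc$name, as.data.frame(cea))
    })
    emit("sensitivity.csv", function(p)
      utils::write.csv(do.call(rbind, rows), p, row.names = FALSE))
  } else {
    psa <- run_psa(ps, iterations, seed, opts)
    draws <- data.frame(iteration = seq_len(iterations),
                        seed = psa$child_seeds)
    for (s in strategies()) {
      draws[[paste0("qalys_", s)]] <- psa$qalys[, s]
      draws[[paste0("cost_", s)]] <- psa_costs(psa)[, s]
    }
    emit("psa_draws.csv", function(p)
      utils::write.csv(draws, p, row.names = FALSE))
    means <- data.frame(strategy = psa$strategies,
                        cost = colMeans(psa_costs(psa)),
                        qalys = colMeans(psa$qalys))
    emit("cea_table.csv", function(p)
      utils::write.csv(as.data.frame(icer_table(means)), p, row.names = FALSE))
    if (analysis == "ceac") {
      emit("ceac.csv", function(p)
        utils::write.csv(as.data.frame(ceac(psa, wtp_grid)), p,
                         row.names = FALSE))
      emit("ceaf.csv", function(p)
        utils::write.csv(as.data.frame(ceaf(psa, wtp_grid)), p,
                         row.names = FALSE))
    }
    if (analysis == "voi") {
      wtp <- as.numeric(config$wtp %||% 50000)
      vs <- voi_summary(psa, wtp,
                        annual_count = config$annual_count %||% 352000,
                        usable_years = config$usable_years %||% 3)
      groups <- config$evppi_groups %||% character(0)
      evppi <- lapply(groups, function(g)
        evppi_nested(ps, g, wtp,
                     outer_n = config$evppi_outer_n %||% 100,
                     inner_n = config$evppi_inner_n %||% 200,
                     seed = seed, opts))
      names(evppi) <- groups
      emit("voi.json", function(p)
        jsonlite::write_json(list(
          wtp = wtp, evpi_pp = vs$evpi_pp,
          population_voi = vs$population_voi,
          qaly_equivalent = vs$qaly_equivalent,
          assumptions = vs$assumptions,
          evppi_pp = evppi,
          evpi_curve = evpi_curve(psa, wtp_grid)),
          p, auto_unbox = TRUE, digits = NA))
    }
  }

  manifest <- list(
    analysis = analysis,
    seed = seed,
    iterations = if (analysis %in% c("psa", "ceac", "voi")) iterations else NULL,
    params = params_path,
    params_md5 = unname(tools::md5sum(params_path)),
    package_version = as.character(utils::packageVersion("mtcea")),
    options = opts[c("include_time_costs", "delayed_efficacy",
                     "apm_progression_multiplier")],
    files = basename(written))
  emit("manifest.json", function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE))
  ok <- TRUE
  message(sprintf("wrote %d file(s) to %s", length(written), out_dir))
  invisible(written)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
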