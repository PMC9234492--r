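#' Pipeline run configuration
#'
#' A single seeded configuration for the end-to-end run: which stages to
#' execute, the field-trial design and event parameters, the economic
#' scenario, Monte Carlo size and conjoint settings. The top-level seed is
#' fanned out to fixed per-stage child seeds, so disabling one stage never
#' shifts another stage's random stream.
#'
#' @param seed integer seed (mandatory).
#' @param stages named logical vector toggling `trial`, `segregation`,
#'   `quantification`, `extraction`, `tea`, `conjoint`.
#' @param design a [trial_design()].
#' @param event_params event parameter table (default
#'   [default_event_params()]).
#' @param scenario a [scenario_inputs()].
#' @param n_reps Monte Carlo repetitions.
#' @param conjoint list of conjoint settings (`n_respondents`,
#'   `gm_partworth`, `heterogeneity_sd`, `n_iter`, `burn_in`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed,
                       stages = c(trial = TRUE, segregation = TRUE,
                                  quantification = TRUE, extraction = TRUE,
                                  tea = TRUE, conjoint = FALSE),
                       design = trial_design(),
                       event_params = default_event_params(),
                       scenario = scenario_inputs(),
                       n_reps = 100000,
                       conjoint = list(n_respondents = 200,
                                       gm_partworth = 0.8,
                                       heterogeneity_sd = 0.5,
                                       n_iter = 1500, burn_in = 750)) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stop_if_not_count(seed, "seed", min = 0L)
  all_stages <- c("trial", "segregation", "quantification", "extraction",
                  "tea", "conjoint")
  st <- stats::setNames(rep(TRUE, length(all_stages)), all_stages)
  st[names(stages)] <- stages
  structure(list(seed = as.integer(seed), stages = st, design = design,
                 event_params = event_params, scenario = scenario,
                 n_reps = n_reps, conjoint = conjoint),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Expects a top-level `seed` key; other keys (`stages`, `scenario` with
#' `D`, `C` and `EY`/`PY`/`P` min/max/mode blocks, `n_reps`, `conjoint`)
#' override the defaults of [run_config()].
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must contain a top-level `seed` key",
                            call. = FALSE)
  args <- list(seed = y$seed)
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  if (!is.null(y$n_reps)) args$n_reps <- y$n_reps
  if (!is.null(y$scenario)) {
    s <- y$scenario
    tri <- function(b, fallback) if (is.null(b)) fallback
      else triangular_dist(b$min, b$max, b$mode)
    def <- scenario_inputs()
    args$scenario <- scenario_inputs(
      D = if (is.null(s$D)) def$D else s$D,
      C = if (is.null(s$C)) def$C else s$C,
      EY = tri(s$EY, def$EY), PY = tri(s$PY, def$PY), P = tri(s$P, def$P))
  }
  if (!is.null(y$conjoint)) {
    def <- formals(run_config)$conjoint
    cj <- eval(def)
    cj[names(y$conjoint)] <- y$conjoint
    args$conjoint <- cj
  }
  do.call(run_config, args)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in dependency order — synthesize the trial,
#' classify segregation, quantify synthetic chromatograms, account for
#' extraction, run the deterministic scenario plus Monte Carlo, optionally
#' fit the conjoint model — and returns a report bundle. Reruns with the
#' same configuration reproduce every output exactly.
#'
#' @param config a [run_config()].
#' @return an object of class `cgp_report` (a named list of stage results
#'   plus a `provenance` block).
#' @export
#' @examples
#' rep <- run_pipeline(run_config(seed = 1, n_reps = 1000))
#' names(rep)
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage_index <- c(trial = 1L, segregation = 2L, quantification = 3L,
                   extraction = 4L, tea = 5L, conjoint = 6L)
  seeds <- vapply(stage_index, function(i) child_seed(config$seed, i),
                  integer(1))
  report <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (config$stages[["trial"]]) {
    records <- run_stage("trial", generate_trial(config$design,
                                                 config$event_params,
                                                 seed = seeds[["trial"]]))
    agg <- stats::aggregate(
      cbind(biomass_dw, cgp_fraction) ~ event_id, records, mean)
    agg$cgp_per_plant <- cgp_per_plant(agg$biomass_dw, agg$cgp_fraction)
    report$trial <- list(n_records = nrow(records),
                         event_means = agg,
                         records = records)
  }
  if (config$stages[["segregation"]]) {
    report$segregation <- run_stage("segregation", {
      ep <- config$event_params
      ep <- ep[ep$locus_count > 0, ]
      counts <- data.frame(
        event_id = ep$event_id, n_seeds = 150L,
        n_resistant = vapply(seq_len(nrow(ep)), function(i)
          generate_segregation_counts(ep$locus_count[i], 150,
            seed = child_seed(seeds[["segregation"]], i))$n_resistant,
          integer(1)))
      classify_events(counts)
    })
  }
  if (config$stages[["quantification"]]) {
    report$quantification <- run_stage("quantification", {
      conc <- c(0.5, 1, 2, 5)
      chroms <- lapply(seq_along(conc), function(i)
        generate_chromatogram(conc[i], noise_sd = 0.5,
                              seed = child_seed(seeds[["quantification"]], i)))
      q <- quantify_samples(chroms, sample_id = paste0("std_", conc))
      q$true_concentration <- conc
      q
    })
  }
  if (config$stages[["extraction"]]) {
    report$extraction <- run_stage("extraction", {
      lab <- simulate_extraction(100, default_protocol("lyophilized"))
      mats <- c("dried_leaf", "silage")
      data.frame(
        material = c("lyophilized", mats),
        overall_recovery = c(lab$overall_recovery,
                             vapply(mats, function(m)
                               simulate_extraction(100,
                                 default_protocol(m))$overall_recovery,
                               numeric(1))),
        efficiency_vs_lab = c(100, vapply(mats, function(m)
          extraction_efficiency(
            simulate_extraction(100, default_protocol(m))$recovered_cgp,
            lab$recovered_cgp), numeric(1))))
    })
  }
  if (config$stages[["tea"]]) {
    report$tea <- run_stage("tea", {
      tab <- scenario_table(config$scenario)
      mc <- run_monte_carlo(config$scenario, n_reps = config$n_reps,
                            seed = seeds[["tea"]], keep_samples = FALSE)
      list(scenario_table = tab, monte_carlo = mc,
           fine_chemical = list(mass_kg_ha = 60, price_usd_kg = 3300,
                                revenue_usd_ha =
                                  fine_chemical_revenue(60, 3300)))
    })
  }
  if (config$stages[["conjoint"]]) {
    report$conjoint <- run_stage("conjoint", {
      cj <- config$conjoint
      des <- build_design(seed = child_seed(seeds[["conjoint"]], 1))
      mu <- stats::setNames(rep(0, ncol(des$X)), colnames(des$X))
      mu["material.GM_bioplastic"] <- cj$gm_partworth
      cd <- generate_choice_data(des, mu, cj$heterogeneity_sd,
                                 cj$n_respondents,
                                 seed = child_seed(seeds[["conjoint"]], 2))
      post <- fit_hb_mnl(cd, n_iter = cj$n_iter, burn_in = cj$burn_in,
                         seed = child_seed(seeds[["conjoint"]], 3),
                         keep_respondent_draws = FALSE)
      list(posterior = post,
           gm_summary = summarize_partworth(post, "material.GM_bioplastic"))
    })
  }
  report$provenance <- list(
    package = "cgpfield",
    version = as.character(utils::packageVersion("cgpfield")),
    seed = config$seed,
    stage_seeds = as.list(seeds[config$stages[names(stage_index)]]),
    config_hash = config_hash(config))
  structure(report, class = "cgp_report")
}

# md5 of the serialized configuration (text form, platform-stable)
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config, digits.d = 15)), f)
  unname(tools::md5sum(f))
}

#' Write a pipeline report
#'
#' Writes the report bundle as schema-checked JSON plus a human-readable
#' text rendering of the scenario table (Min/Max/Mode layout) and Monte
#' Carlo six-number summaries.
#'
#' @param report a `cgp_report` from [run_pipeline()].
#' @param path output path for the JSON file; a sibling `.txt` file is
#'   written next to it.
#' @return invisible list with the two file paths.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "cgp_report"))
  out <- list(provenance = report$provenance)
  if (!is.null(report$trial))
    out$trial <- list(n_records = report$trial$n_records,
                      event_means = report$trial$event_means)
  if (!is.null(report$segregation)) out$segregation <- report$segregation
  if (!is.null(report$quantification))
    out$quantification <- report$quantification
  if (!is.null(report$extraction)) out$extraction <- report$extraction
  if (!is.null(report$tea)) {
    tab <- report$tea$scenario_table
    mc <- report$tea$monte_carlo
    out$tea <- list(
      scenario_table = tab$display,
      monte_carlo = list(n_reps = mc$n_reps,
                         E = as.list(mc$summary_E),
                         R = as.list(mc$summary_R)),
      fine_chemical = report$tea$fine_chemical)
  }
  if (!is.null(report$conjoint))
    out$conjoint <- list(
      gm_summary = report$conjoint$gm_summary,
      acceptance_rate = report$conjoint$posterior$acceptance_rate)
  validate_report(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  txt <- sub("\\.json$", ".txt", path)
  if (txt == path) txt <- paste0(path, ".txt")
  con <- file(txt, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("cgpfield report (seed %d, config %s)", out$provenance$seed,
    out$provenance$config_hash)
  if (!is.null(out$tea)) {
    w("\nScenario table (Min / Max / Mode)")
    d <- out$tea$scenario_table
    for (i in seq_len(nrow(d)))
      w("  %-11s %12s %12s %12s", d$quantity[i],
        format(d$min[i], big.mark = ","), format(d$max[i], big.mark = ","),
        format(d$mode[i], big.mark = ","))
    w("\nMonte Carlo (%s reps): Min 1st-Qu Median Mean 3rd-Qu Max",
      format(out$tea$monte_carlo$n_reps, big.mark = ","))
    w("  CGP extracted [kg/ha]: %s",
      paste(round(unlist(out$tea$monte_carlo$E), 1), collapse = "  "))
    w("  Revenue [USD/ha]:      %s",
      paste(format(round(unlist(out$tea$monte_carlo$R)), big.mark = ","),
            collapse = "  "))
  }
  if (!is.null(out$segregation)) {
    w("\nSegregation classification")
    s <- out$segregation
    for (i in seq_len(nrow(s)))
      w("  event %-5s %3d/%3d resistant -> %s", s$event_id[i],
        s$n_resistant[i], s$n_seeds[i], s$label[i])
  }
  invisible(list(json = path, txt = txt))
}

#' Structurally validate a report against the shipped schema
#'
#' Checks the report list against the JSON schema document shipped at
#' `inst/schema/report-schema.json` (required keys and basic types; the
#' validator implements the subset of JSON Schema the document uses).
#'
#' @param report named list as written by [write_report()].
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(report) {
  schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                            package = "cgpfield"))
  check_obj <- function(obj, sch, where) {
    req <- unlist(sch$required)
    missing <- setdiff(req, names(obj))
    if (length(missing))
      stop(sprintf("report%s is missing required field(s): %s", where,
                   paste(missing, collapse = ", ")), call. = FALSE)
    for (k in intersect(names(sch$properties), names(obj))) {
      pr <- sch$properties[[k]]
      if (!is.null(pr$type) && pr$type == "object")
        check_obj(obj[[k]], pr, paste0(where, "$", k))
    }
  }
  check_obj(report, schema, "")
  invisible(TRUE)
}
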