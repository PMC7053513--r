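# Readers and writers for the pipeline's interface files.  All tabular
# outputs are TSV with a provenance header comment (tool version + config
# hash); writes are atomic (temp file + rename).

osmoflux_version <- function() {
  as.character(utils::packageVersion("osmoflux"))
}

config_hash <- function(x) {
  # order-independent digest of a config list; no external digest package
  if (length(x)) x <- x[order(names(x))]
  s <- paste(deparse(x), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% .Machine$integer.max)
}

write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_tsv_with_header <- function(df, path, config = list()) {
  write_atomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("# osmoflux %s config=%s", osmoflux_version(),
                       config_hash(config)), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' Write / read a MID table
#'
#' TSV with columns `fragment_id`, `mass_shift`, `fraction`, `sd`.
#' @param df MID data frame.
#' @param path file path.
#' @param config config list recorded in the header hash.
#' @return the path (write) or the data frame (read).
#' @export
write_mid_table <- function(df, path, config = list()) {
  write_tsv_with_header(df, path, config)
}

#' @rdname write_mid_table
#' @export
read_mid_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write / read a rates table
#' @inheritParams write_mid_table
#' @export
write_rates_table <- function(df, path, config = list()) {
  write_tsv_with_header(df, path, config)
}

#' @rdname write_rates_table
#' @export
read_rates_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write fitted fluxes with confidence bounds
#'
#' @param fit an `mfa_fit`.
#' @param ci optional `mfa_ci`.
#' @param path output TSV.
#' @param config config list recorded in the header.
#' @return the path, invisibly.
#' @export
write_flux_table <- function(fit, path, ci = NULL, config = list()) {
  net <- fit$fluxes$net
  df <- data.frame(reaction = names(net), net_flux = unname(net),
                   stringsAsFactors = FALSE)
  exch <- fit$fluxes$exchange
  df$exchange_flux <- ifelse(df$reaction %in% names(exch),
                             exch[df$reaction], NA_real_)
  if (!is.null(ci)) {
    m <- match(df$reaction, ci$intervals$reaction)
    df$ci_lower <- ci$intervals$lower[m]
    df$ci_upper <- ci$intervals$upper[m]
  }
  write_tsv_with_header(df, path, config)
  invisible(path)
}

#' Export a two-column (reaction, flux) table for network-visualization
#' tools
#' @param fluxes a `flux_vector` or `mfa_fit`.
#' @param path output TSV.
#' @return the path, invisibly.
#' @export
export_flux_map <- function(fluxes, path) {
  if (inherits(fluxes, "mfa_fit")) fluxes <- fluxes$fluxes
  df <- data.frame(reaction = names(fluxes$net), flux = unname(fluxes$net))
  write_atomic(function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE), path)
  invisible(path)
}

CONFIG_KEYS <- c("restarts", "seed", "maxiter", "n_monte_carlo", "nacl",
                 "mid_sd", "rate_rel_sd", "tolerance")

#' Read a run configuration
#'
#' YAML file with optimizer and scenario settings; unknown keys are
#' rejected.
#' @param path YAML file.
#' @return named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ",")),
         call. = FALSE)
  cfg
}

#' Write a complete synthetic problem bundle
#'
#' Emits everything a fit run needs into a directory: the model CSV, one
#' raw MID table per tracer, the rate and biomass tables, a config YAML
#' and `truth.json` with the hidden true flux vector.
#'
#' @param scenario an `mfa_scenario`.
#' @param dir output directory (created if needed).
#' @param seed seed used for the noise draws.
#' @return the directory, invisibly.
#' @export
write_bundle <- function(scenario, dir, seed = scenario$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- list(seed = seed, nacl = scenario$nacl, mid_sd = scenario$mid_sd,
              rate_rel_sd = scenario$rate_rel_sd)
  file.copy(bmeg_model_file(), file.path(dir, "model.csv"), overwrite = TRUE)
  exps <- list(c1 = generate_tracer_experiment(scenario, "c1", seed = seed),
               u50 = generate_tracer_experiment(scenario, "u50", seed = seed + 1L))
  for (nm in names(exps))
    write_mid_table(exps[[nm]]$mids, file.path(dir, paste0("mids_", nm, ".tsv")), cfg)
  write_rates_table(exps$c1$rates, file.path(dir, "rates.tsv"), cfg)
  demands <- interpolate_biomass(load_biomass(), scenario$nacl)
  write_atomic(function(tmp) utils::write.csv(demands, tmp, row.names = FALSE),
               file.path(dir, "biomass.csv"))
  write_atomic(function(tmp) yaml::write_yaml(cfg, tmp), file.path(dir, "config.yaml"))
  write_atomic(function(tmp)
    jsonlite::write_json(list(net = as.list(scenario$truth$net),
                              exchange = as.list(scenario$truth$exchange),
                              nacl = scenario$nacl, seed = seed),
                         tmp, auto_unbox = TRUE, digits = NA),
    file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read a problem bundle into an estimation problem
#'
#' @param dir directory written by [write_bundle()] (or hand-assembled in
#'   the same layout).
#' @param settings optimizer settings overriding the bundle config.
#' @return list with `problem` (an `mfa_problem`), `scenario`, and
#'   `truth` (or NULL when absent).
#' @export
read_bundle <- function(dir, settings = list()) {
  cfg <- read_config(file.path(dir, "config.yaml"))
  scenario <- osmoflux_scenario(nacl = cfg$nacl %||% 0,
                                mid_sd = cfg$mid_sd %||% 0.005,
                                rate_rel_sd = cfg$rate_rel_sd %||% 0.03,
                                seed = cfg$seed %||% 1L)
  exps <- list()
  for (nm in c("c1", "u50")) {
    f <- file.path(dir, paste0("mids_", nm, ".tsv"))
    if (!file.exists(f)) next
    exps[[nm]] <- list(mids = read_mid_table(f),
                       rates = read_rates_table(file.path(dir, "rates.tsv")),
                       tracer = scenario$tracers[[nm]])
  }
  if (!length(exps)) stop("bundle contains no MID tables", call. = FALSE)
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = TRUE)
    truth <- flux_vector(unlist(tj$net), unlist(tj$exchange))
  }
  problem <- scenario_problem(scenario, exps,
                              utils::modifyList(list(seed = cfg$seed %||% 1L), settings))
  list(problem = problem, scenario = scenario, truth = truth)
}
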