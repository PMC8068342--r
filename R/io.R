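## Config-driven drivers and table writers.  These are the package's
## batch interface: a YAML/JSON config in, TSV tables and a JSON metadata
## record out.

#' Read a run configuration
#'
#' Reads a YAML or JSON configuration file (or passes a list through).
#' Recognised fields are documented under [run_yield_table()].
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, or a list.
#' @return A named list.
#' @export
read_config <- function(config) {
  if (is.list(config)) return(config)
  if (!file.exists(config)) stopf("config file '%s' not found", config)
  if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
  else yaml::read_yaml(config)
}

quality_from_config <- function(spec, model = NULL) {
  if (inherits(spec, "radiation_quality")) return(spec)
  if (is.character(spec)) stopf("unknown quality '%s'; supply a parameter list with fields name, let_keV_um, cluster_rate_rho, multiplicity_nu, p_strand_break, nseg (plus optional scavenger/oxygen presets)", spec)
  scav <- if (!is.null(spec$scavenger_preset)) scavenger_preset(spec$scavenger_preset)
          else if (!is.null(spec$scavenger)) do.call(scavenger_params, spec$scavenger)
          else scavenger_preset("cobalt60")
  oxy <- if (!is.null(spec$oxygen)) do.call(oxygen_params, spec$oxygen) else oxygen_params()
  radiation_quality(spec$name, spec$let_keV_um %||% 0, spec$cluster_rate_rho,
                    spec$multiplicity_nu, spec$p_strand_break, spec$nseg,
                    scavenger = scav, oxygen = oxy)
}

#' Run a damage-yield table from a configuration
#'
#' Simulates one yield row per (quality, condition) combination and
#' writes a TSV in the conventional column order (BD, SSB, SSB+, 2SSB,
#' DSB, DSB+, DSB++, Total SSB, Total DSB, Total Damage) with paired
#' value/SE columns, percent-reduction columns relative to each quality's
#' first (baseline) condition, and a JSON metadata record (seeds, survival
#' factors, cluster counts).
#'
#' Config fields: `qualities` (list of quality parameter lists, see
#' [run_yield_table()] examples in the vignette), `conditions` (list of
#' `{dmso_M, o2_percent}`), `n_clusters`, `dose`, `seed`, `output`
#' (TSV path) and `metadata` (JSON path); the last two default to `NULL`
#' (nothing written, table returned).
#'
#' @param config list or path accepted by [read_config()].
#' @param style `"paired"` writes numeric value/se columns; `"pm"` writes
#'   presentation strings `"value ± se"` rounded to two decimals.
#' @return The yield table (data frame), invisibly if written to file.
#' @export
run_yield_table <- function(config, style = c("paired", "pm")) {
  style <- match.arg(style)
  cfg <- read_config(config)
  if (is.null(cfg$qualities) || !length(cfg$qualities)) stopf("config field 'qualities' is required")
  if (is.null(cfg$conditions) || !length(cfg$conditions)) stopf("config field 'conditions' is required")
  seed <- as.integer(cfg$seed %||% 1L)
  scfg <- simulation_config(dose = cfg$dose %||% 1,
                            n_clusters = cfg$n_clusters %||% 1e5, seed = seed)
  rows <- list(); meta_runs <- list()
  for (qspec in cfg$qualities) {
    q <- quality_from_config(qspec)
    base <- NULL
    for (cond in cfg$conditions) {
      env <- environment_condition(cond$dmso_M %||% 0, cond$o2_percent %||% 21)
      y <- simulate_damage_spectrum(q, env, scfg)
      v <- yields_named(y); se <- c(y$table$se, y$totals$se)
      if (is.null(base)) base <- v
      row <- data.frame(quality = q$name, dmso_M = env$dmso_M,
                        o2_percent = env$o2_percent)
      for (k in seq_along(v)) {
        row[[paste0(names(v)[k], "_yield")]] <- v[k]
        row[[paste0(names(v)[k], "_se")]] <- se[k]
        row[[paste0(names(v)[k], "_pctdown")]] <- percent_reduction(base[k], v[k])
      }
      rows[[length(rows) + 1L]] <- row
      meta_runs[[length(meta_runs) + 1L]] <-
        list(quality = q$name, dmso_M = env$dmso_M, o2_percent = env$o2_percent,
             survival = y$meta$survival %||% 1, n_clusters = y$totals["total_damage", "count"])
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (style == "pm") {
    ycols <- grep("_yield$", names(tab), value = TRUE)
    for (yc in ycols) {
      sc <- sub("_yield$", "_se", yc)
      tab[[sub("_yield$", "", yc)]] <- sprintf("%.2f ± %.2f", tab[[yc]], tab[[sc]])
    }
    tab <- tab[, !grepl("_yield$|_se$|_pctdown$", names(tab))]
  }
  if (!is.null(cfg$output)) {
    utils::write.table(tab, cfg$output, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cfg$metadata)) write_run_metadata(cfg$metadata, seed, scfg, meta_runs)
    return(invisible(tab))
  }
  tab
}

#' Run a mutation-frequency table from a configuration
#'
#' Long-format repair driver: one row per (quality, pathway, condition).
#' Config fields as in [run_yield_table()] plus `pathways` and optional
#' `repair` overrides ([repair_params()] fields).
#'
#' @param config list or path accepted by [read_config()].
#' @return Data frame `radiation, pathway, dmso_M, o2_percent, value, se,
#'   n_clusters`; written as TSV when `output` is configured.
#' @export
run_repair_table <- function(config) {
  cfg <- read_config(config)
  if (is.null(cfg$qualities) || !length(cfg$qualities)) stopf("config field 'qualities' is required")
  conds <- cfg$conditions
  if (is.null(conds) || !length(conds)) stopf("config field 'conditions' is required")
  dmso <- vapply(conds, function(x) x$dmso_M %||% 0, numeric(1))
  o2 <- unique(vapply(conds, function(x) x$o2_percent %||% 21, numeric(1)))
  if (length(o2) != 1L) stopf("run_repair_table() sweeps DMSO at a single oxygen tension")
  scfg <- simulation_config(dose = cfg$dose %||% 1,
                            n_clusters = cfg$n_clusters %||% 1e5,
                            seed = as.integer(cfg$seed %||% 1L))
  out <- list()
  for (qspec in cfg$qualities) {
    q <- quality_from_config(qspec)
    out[[length(out) + 1L]] <-
      pathway_sweep(q, dmso_grid = dmso,
                    pathways = cfg$pathways %||% REPAIR_PATHWAYS,
                    config = scfg, o2_percent = o2,
                    repair_args = cfg$repair %||% list())
  }
  tab <- do.call(rbind, out)
  if (!is.null(cfg$output)) {
    utils::write.table(tab, cfg$output, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Run an RBE-vs-DMSO or OER-vs-oxygen curve from a configuration
#'
#' @param kind `"rbe-dmso"` (requires a `reference` quality in the
#'   config) or `"oer-o2"`.
#' @param config list or path; fields as in [run_yield_table()] plus
#'   `grid` (numeric sweep grid) and, for RBE, `reference`.
#' @return The sweep data frame from [dmso_sweep()] or [o2_sweep()].
#' @export
run_sweep <- function(kind = c("rbe-dmso", "oer-o2"), config) {
  kind <- match.arg(kind)
  cfg <- read_config(config)
  q <- quality_from_config(cfg$qualities[[1L]])
  scfg <- simulation_config(dose = cfg$dose %||% 1,
                            n_clusters = cfg$n_clusters %||% 1e5,
                            seed = as.integer(cfg$seed %||% 1L))
  tab <- if (kind == "rbe-dmso") {
    if (is.null(cfg$reference)) stopf("RBE sweep needs a 'reference' quality in the config")
    dmso_sweep(q, quality_from_config(cfg$reference),
               dmso_grid = cfg$grid %||% seq(0, 2, 0.25), config = scfg)
  } else {
    o2_sweep(q, o2_grid = cfg$grid %||% c(0.001, 0.01, 0.1, 1, 2, 5, 21, 100),
             config = scfg)
  }
  if (!is.null(cfg$output)) {
    utils::write.table(tab, cfg$output, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

write_run_metadata <- function(path, seed, scfg, runs) {
  meta <- list(tool = "mcdamage",
               version = as.character(utils::packageVersion("mcdamage")),
               root_seed = seed,
               dose = scfg$dose, n_clusters = scfg$n_clusters,
               per_cell_factor = scfg$per_cell_factor,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               runs = runs)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(meta)
}

#' Write and re-read a damage-yield TSV
#'
#' `write_yields()` stores a `damage_yields` object as a TSV with full
#' numeric precision (paired value/SE columns in the conventional class
#' order), so `read_yields()` round-trips it exactly.
#'
#' @param x a `damage_yields` object.
#' @param file output path.
#' @return `write_yields()` the path invisibly; `read_yields()` a data
#'   frame with columns `class`, `count`, `yield`, `se`.
#' @export
write_yields <- function(x, file) {
  stopifnot(inherits(x, "damage_yields"))
  d <- as.data.frame(x)
  utils::write.table(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_yields
#' @export
read_yields <- function(file) {
  utils::read.delim(file, stringsAsFactors = FALSE)
}
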