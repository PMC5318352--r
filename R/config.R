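# Structured run configuration: load/validate/save, and the one-call runner
# that writes the full artifact bundle (family CSV, p-box CSVs + JSON
# summaries, fractile-MF JSONs, run manifest).

.config_schema <- c("model", "parameters", "expression", "n_mc", "seed",
                    "alpha_steps", "fractiles", "range_percentiles",
                    "quantile_mode", "variance_divisor", "refine_nonmonotone",
                    "out_dir")

# parse one parameter entry from its serialized form
parse_param <- function(x, name) {
  if (is.numeric(x) && length(x) == 1) return(x)
  if (!is.list(x)) stop(sprintf("parameter '%s': unrecognized form", name), call. = FALSE)
  if (!is.null(x$dist)) {
    return(switch(x$dist,
      normal = dist_normal(x$mean, x$sd),
      constant = dist_constant(x$value),
      stop(sprintf("parameter '%s': unknown dist '%s'", name, x$dist), call. = FALSE)
    ))
  }
  if (!is.null(x$umf) && !is.null(x$lmf)) {
    return(ivfn(umf = parse_param(x$umf, paste0(name, "$umf")),
                lmf = parse_param(x$lmf, paste0(name, "$lmf"))))
  }
  if (!is.null(x$type) && x$type %in% c("tri", "trap")) {
    k <- as.numeric(x$knots)
    h <- if (is.null(x$height)) 1 else x$height
    if (x$type == "tri") {
      if (length(k) != 3) stop(sprintf("parameter '%s': tri needs 3 knots", name), call. = FALSE)
      return(gfn(k[1], k[2], k[3], height = h))
    }
    if (length(k) != 4) stop(sprintf("parameter '%s': trap needs 4 knots", name), call. = FALSE)
    return(gfn(k[1], k[2], k[3], k[4], height = h))
  }
  if (!is.null(x$value)) return(as.numeric(x$value))
  stop(sprintf("parameter '%s': unrecognized form", name), call. = FALSE)
}

serialize_param <- function(p) {
  if (inherits(p, "gfn")) {
    if (p$b == p$c) list(type = "tri", knots = c(p$a, p$b, p$d), height = p$w)
    else list(type = "trap", knots = c(p$a, p$b, p$c, p$d), height = p$w)
  } else if (inherits(p, "ivfn")) {
    list(umf = serialize_param(p$umf), lmf = serialize_param(p$lmf))
  } else if (inherits(p, "dist_spec")) {
    if (p$family == "normal") list(dist = "normal", mean = p$mean, sd = p$sd)
    else list(dist = "constant", value = p$value)
  } else {
    as.numeric(p)
  }
}

#' Load, validate and save run configurations
#'
#' A run configuration names the model (a built-in like `"arsenic"`, or an
#' arithmetic `expression` over declared `parameters`), the engine settings
#' (`n_mc`, `seed`, `alpha_steps`) and the summary settings (`fractiles`,
#' `range_percentiles`, `quantile_mode`). Files are YAML (`.yml`/`.yaml`) or
#' JSON (`.json`), chosen by extension. Validation is exhaustive: every
#' schema violation is reported, unknown keys are listed by name, and a
#' missing `seed` is an error (reproducibility is not optional).
#' `save_run_config()` then `load_run_config()` is the identity on the
#' schema fields.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `load_run_config()`: a validated list of class `"run_config"`.
#' @examples
#' cfg_file <- system.file("extdata", "arsenic.yaml", package = "fuzzybox")
#' cfg <- load_run_config(cfg_file)
#' @export
load_run_config <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    stop("config must be .yaml/.yml or .json", call. = FALSE)
  }
  as_run_config(raw)
}

#' @rdname load_run_config
#' @param x A bare list with the schema fields (e.g. parsed from a file).
#' @export
as_run_config <- function(x) {
  stopifnot(is.list(x))
  problems <- character(0)
  unknown <- setdiff(names(x), .config_schema)
  if (length(unknown)) {
    problems <- c(problems, paste0("unknown key: ", unknown))
  }
  if (is.null(x$seed)) problems <- c(problems, "missing required field: seed")
  if (is.null(x$model) && is.null(x$expression)) {
    problems <- c(problems, "one of 'model' (built-in name) or 'expression' is required")
  }
  if (!is.null(x$expression) && is.null(x$parameters)) {
    problems <- c(problems, "'expression' requires 'parameters'")
  }
  cfg <- list(
    model = x$model,
    parameters = x$parameters,
    expression = x$expression,
    n_mc = x$n_mc %||% 5000,
    seed = x$seed,
    alpha_steps = x$alpha_steps %||% 10,
    fractiles = unlist(x$fractiles) %||% c(0.95, 0.85),
    range_percentiles = unlist(x$range_percentiles) %||% c(0.005, 0.995),
    quantile_mode = x$quantile_mode %||% "empirical",
    variance_divisor = x$variance_divisor %||% "population",
    refine_nonmonotone = isTRUE(x$refine_nonmonotone),
    out_dir = x$out_dir
  )
  if (!is.null(cfg$model) && !identical(cfg$model, "arsenic") && is.null(cfg$expression)) {
    problems <- c(problems, sprintf("unknown built-in model: '%s'", cfg$model))
  }
  if (any(cfg$fractiles <= 0 | cfg$fractiles >= 1)) {
    problems <- c(problems, "fractiles must lie strictly in (0, 1)")
  }
  if (length(cfg$range_percentiles) != 2 ||
      any(cfg$range_percentiles <= 0 | cfg$range_percentiles >= 1) ||
      cfg$range_percentiles[1] >= cfg$range_percentiles[2]) {
    problems <- c(problems, "range_percentiles must be two increasing values in (0, 1)")
  }
  if (!cfg$quantile_mode %in% c("empirical", "analytic")) {
    problems <- c(problems, "quantile_mode must be 'empirical' or 'analytic'")
  }
  if (length(problems)) {
    stop("invalid run config:\n  ", paste(problems, collapse = "\n  "), call. = FALSE)
  }
  # parse declared parameters (also rejects generalized IVFNs later, at
  # engine entry)
  if (!is.null(cfg$parameters)) {
    cfg$parameters <- mapply(parse_param, cfg$parameters, names(cfg$parameters),
                             SIMPLIFY = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' @rdname load_run_config
#' @param config A `"run_config"` object.
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!is.null(out$parameters)) {
    out$parameters <- lapply(out$parameters, serialize_param)
  }
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

# build a hybrid_model from a run_config
config_model <- function(config) {
  if (!is.null(config$expression)) {
    expr <- parse(text = config$expression)[[1]]
    nms <- names(config$parameters)
    evaluator <- rlang::new_function(
      args = stats::setNames(replicate(length(nms), rlang::missing_arg()), nms),
      body = expr
    )
    hybrid_model(evaluator, config$parameters, name = config$model %||% "config-model")
  } else {
    arsenic_model()
  }
}

# 9 significant digits everywhere; keeps diffs stable across platforms
fmt_num <- function(x) signif(x, 9)

#' Run a configuration and write the artifact bundle
#'
#' Propagates the configured model and writes, under `out_dir`:
#' `family.csv` (the long-format CDF family), `pbox_umf.csv` /
#' `pbox_lmf.csv` (bounding curves) with `pbox_umf.json` / `pbox_lmf.json`
#' (range/mean/variance interval summaries), one `fractile_p<p>.json` per
#' requested fractile (knots, height and the full alpha table), and
#' `manifest.json` (seed, settings, package version). Identical config and
#' seed give byte-identical CSV/JSON payloads; the timestamp lives only in
#' the manifest.
#'
#' @param config A `"run_config"` from [load_run_config()] /
#'   [as_run_config()].
#' @param out_dir Output directory (created if needed); overrides the
#'   config's `out_dir`.
#' @return Invisibly, a named list of the written file paths.
#' @export
run_config <- function(config, out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) stop("out_dir is required", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- config_model(config)
  fam <- propagate(model, n_mc = config$n_mc, seed = config$seed,
                   alpha_steps = config$alpha_steps,
                   refine_nonmonotone = config$refine_nonmonotone)
  paths <- list()

  fam_long <- tidy.cdf_family(fam)
  fam_long$value <- fmt_num(fam_long$value)
  paths$family <- file.path(out_dir, "family.csv")
  utils::write.csv(fam_long, paths$family, row.names = FALSE)

  for (pass in c("umf", "lmf")) {
    pb <- pbox(fam, pass)
    curves <- tidy.pbox(pb)
    curves$value <- fmt_num(curves$value)
    curves$cumprob <- fmt_num(curves$cumprob)
    paths[[paste0("pbox_", pass, "_csv")]] <- file.path(out_dir, sprintf("pbox_%s.csv", pass))
    utils::write.csv(curves, paths[[paste0("pbox_", pass, "_csv")]], row.names = FALSE)
    rng <- pbox_range(pb, config$range_percentiles[1], config$range_percentiles[2],
                      mode = config$quantile_mode)
    mn <- pbox_mean(pb)
    vr <- pbox_variance(pb, divisor = config$variance_divisor)
    paths[[paste0("pbox_", pass, "_json")]] <- file.path(out_dir, sprintf("pbox_%s.json", pass))
    jsonlite::write_json(
      list(pass = pass,
           range = fmt_num(unclass(rng)), mean = fmt_num(unclass(mn)),
           variance = fmt_num(unclass(vr))),
      paths[[paste0("pbox_", pass, "_json")]], auto_unbox = TRUE, digits = NA
    )
  }

  for (p in config$fractiles) {
    mf <- fractile_mf(fam, p, mode = config$quantile_mode)
    tab <- mf$alpha_table
    tab$lo <- fmt_num(tab$lo); tab$hi <- fmt_num(tab$hi)
    key <- sprintf("fractile_p%s", gsub("\\.", "", format(p)))
    paths[[key]] <- file.path(out_dir, paste0(key, ".json"))
    jsonlite::write_json(
      list(p = p, height = mf$height,
           umf_knots = fmt_num(c(mf$umf$a, mf$umf$b, mf$umf$c, mf$umf$d)),
           lmf_knots = fmt_num(c(mf$lmf$a, mf$lmf$b, mf$lmf$c, mf$lmf$d)),
           alpha_table = tab),
      paths[[key]], auto_unbox = TRUE, digits = NA
    )
  }

  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(model = model$name, seed = config$seed, n_mc = config$n_mc,
         alpha_steps = config$alpha_steps,
         alpha_levels = attr(fam, "alpha_levels"),
         fractiles = config$fractiles,
         range_percentiles = config$range_percentiles,
         quantile_mode = config$quantile_mode,
         variance_divisor = config$variance_divisor,
         package_version = as.character(utils::packageVersion("fuzzybox")),
         timestamp = format(Sys.time(), tz = "UTC")),
    paths$manifest, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
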