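#' Parse a simulation run configuration
#'
#' Reads a declarative YAML file describing a full grid run. Recognised keys:
#'
#' * `trait` — `"binary"` or `"quantitative"`.
#' * `cases`, `ratio` — axis lists for binary designs.
#' * `n` — axis list of total sample sizes for quantitative designs.
#' * `maf`, `penetrance` — axis lists (both trait types).
#' * `baseline` — baseline prevalence scalar (default 0.1).
#' * `replicates` — datasets per cell (default 1000).
#' * `family_level` — optional family-wise significance level; when supplied,
#'   the per-test threshold is `family_level / 40` (binary) or `/ 4`
#'   (quantitative). When absent, the per-trait defaults apply (0.00025
#'   binary, 0.004 quantitative; see [sim_design()]).
#' * `master_seed` (default 1), `workers` (default 1), `output` (optional
#'   path).
#'
#' Unknown keys are rejected by name; the cartesian product of the axis lists
#' forms the grid. `write_config()` serialises a config so that
#' parse -> write -> parse is the identity.
#'
#' @param path path to a YAML configuration file.
#' @return An object of class `run_config` (validated named list).
#' @export
parse_config <- function(path) {
  stopifnot(file.exists(path))
  # keep YAML-1.1 boolean tokens (notably the axis key "n") as literal text;
  # no config field is boolean-valued
  keep <- function(x) x
  raw <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                               "bool#no" = keep))
  if (!is.list(raw) || is.null(names(raw))) {
    stop("config must be a mapping of named keys", call. = FALSE)
  }
  allowed <- c("trait", "cases", "ratio", "n", "maf", "penetrance",
               "baseline", "replicates", "family_level", "master_seed",
               "workers", "output")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- list(
    trait = raw$trait,
    cases = as_axis(raw$cases), ratio = as_axis(raw$ratio),
    n = as_axis(raw$n),
    maf = as_axis(raw$maf), penetrance = as_axis(raw$penetrance),
    baseline = if (is.null(raw$baseline)) 0.1 else as.numeric(raw$baseline),
    replicates = if (is.null(raw$replicates)) 1000L else as.integer(raw$replicates),
    family_level = if (is.null(raw$family_level)) NULL else as.numeric(raw$family_level),
    master_seed = if (is.null(raw$master_seed)) 1L else as.integer(raw$master_seed),
    workers = if (is.null(raw$workers)) 1L else as.integer(raw$workers),
    output = raw$output
  )
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

as_axis <- function(x) if (is.null(x)) NULL else as.numeric(unlist(x))

validate_config <- function(cfg) {
  fail <- function(key, msg) {
    stop(sprintf("invalid config value for '%s': %s", key, msg), call. = FALSE)
  }
  if (is.null(cfg$trait) || !cfg$trait %in% c("binary", "quantitative")) {
    fail("trait", "must be \"binary\" or \"quantitative\"")
  }
  if (cfg$trait == "binary") {
    if (is.null(cfg$cases) || length(cfg$cases) == 0) fail("cases", "axis missing or empty")
    if (any(cfg$cases < 1 | cfg$cases != floor(cfg$cases))) fail("cases", "must be positive integers")
    if (is.null(cfg$ratio) || length(cfg$ratio) == 0) fail("ratio", "axis missing or empty")
    if (any(cfg$ratio < 1)) fail("ratio", "controls-per-case must be >= 1")
  } else {
    if (is.null(cfg$n) || length(cfg$n) == 0) fail("n", "axis missing or empty")
    if (any(cfg$n < 2 | cfg$n != floor(cfg$n))) fail("n", "must be integers >= 2")
  }
  if (is.null(cfg$maf) || length(cfg$maf) == 0) fail("maf", "axis missing or empty")
  if (any(cfg$maf <= 0 | cfg$maf > 0.5)) fail("maf", "must be in (0, 0.5]")
  if (is.null(cfg$penetrance) || length(cfg$penetrance) == 0) fail("penetrance", "axis missing or empty")
  if (any(cfg$penetrance <= 0 | cfg$penetrance > 1)) fail("penetrance", "must be in (0, 1]")
  if (!(cfg$baseline > 0 && cfg$baseline <= 1)) fail("baseline", "must be in (0, 1]")
  if (any(cfg$penetrance < cfg$baseline)) fail("penetrance", "must be >= baseline")
  if (cfg$replicates < 1) fail("replicates", "must be >= 1")
  if (!is.null(cfg$family_level) &&
      !(cfg$family_level > 0 && cfg$family_level < 1)) {
    fail("family_level", "must be in (0, 1)")
  }
  if (cfg$workers < 1) fail("workers", "must be >= 1")
  invisible(cfg)
}

#' @param cfg a `run_config`.
#' @rdname parse_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- Filter(Negate(is.null), unclass(cfg))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Expand a configuration into a list of designs
#'
#' Forms the cartesian product of the config's axis lists and returns one
#' [sim_design()] per cell, in a fixed (row-major) order.
#'
#' @param cfg a [parse_config()] object.
#' @return List of `sim_design` objects.
#' @export
grid_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (cfg$trait == "binary") {
    cells <- expand.grid(n_cases = cfg$cases, ratio = cfg$ratio,
                         maf = cfg$maf, penetrance = cfg$penetrance,
                         KEEP.OUT.ATTRS = FALSE)
    alpha <- if (is.null(cfg$family_level)) NULL else
      alpha_threshold(cfg$family_level, 40)
    lapply(seq_len(nrow(cells)), function(i) {
      sim_design("binary",
                 n_cases = cells$n_cases[i], ratio = cells$ratio[i],
                 maf = cells$maf[i], penetrance = cells$penetrance[i],
                 baseline = cfg$baseline, replicates = cfg$replicates,
                 alpha = alpha)
    })
  } else {
    cells <- expand.grid(n = cfg$n, maf = cfg$maf,
                         penetrance = cfg$penetrance, KEEP.OUT.ATTRS = FALSE)
    alpha <- if (is.null(cfg$family_level)) NULL else
      alpha_threshold(cfg$family_level, 4)
    lapply(seq_len(nrow(cells)), function(i) {
      sim_design("quantitative",
                 n = cells$n[i], maf = cells$maf[i],
                 penetrance = cells$penetrance[i],
                 baseline = cfg$baseline, replicates = cfg$replicates,
                 alpha = alpha)
    })
  }
}

#' Write a power-estimate table with a reproducibility header
#'
#' Serialises a [run_grid()] result as tab-separated values, preceded by `#`
#' comment lines recording the package version, master seed and a fingerprint
#' of the configuration, so a result file identifies the run that produced
#' it. Output is byte-stable for a fixed table and header.
#'
#' @param tab a `data.frame` of power estimates.
#' @param path output path.
#' @param master_seed seed recorded in the header.
#' @param cfg optional `run_config` fingerprinted in the header.
#' @return The path, invisibly.
#' @export
write_power_table <- function(tab, path, master_seed = NA, cfg = NULL) {
  stopifnot(is.data.frame(tab))
  hdr <- c(
    sprintf("# phewaspower %s", as.character(packageVersion("phewaspower"))),
    sprintf("# master_seed: %s", as.character(master_seed)),
    sprintf("# config_hash: %s", config_hash(cfg))
  )
  writeLines(hdr, path)
  data.table::fwrite(tab, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_power_table
#' @param skip_comments ignored columns prefix; reads a table written by
#'   `write_power_table()`.
#' @export
read_power_table <- function(path, skip_comments = "#") {
  data.table::fread(path, sep = "\t", skip = 3L)
}

# 31-bit rolling fingerprint of the deparsed config (stable across sessions).
config_hash <- function(cfg) {
  if (is.null(cfg)) return("none")
  txt <- paste(deparse(Filter(Negate(is.null), unclass(cfg))), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
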