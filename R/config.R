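## Structured run configuration: one human-readable YAML file drives the
## whole pipeline; every section is validated by the same constructors the
## R API uses, so a band gap or an out-of-range probability fails at load
## time with the offending key named.

section_builders <- list(
  cohort = function(x) {
    x$n <- x$n %||% 10000
    if (!is.null(x$smoking_probs)) x$smoking_probs <- unlist(x$smoking_probs)
    if (!is.null(x$entry_age_range)) x$entry_age_range <- unlist(x$entry_age_range)
    if (!is.null(x$log_hr_tertile)) x$log_hr_tertile <- unlist(x$log_hr_tertile)
    if (!is.null(x$log_hr_smoking)) x$log_hr_smoking <- unlist(x$log_hr_smoking)
    x$life_table <- build_life_table(x$life_table)
    check_section_keys(x, cohort_spec, "cohort")
    do.call(cohort_spec, x)
  },
  natural_history = function(x) {
    if (!is.null(x$growth)) {
      g <- x$growth
      if (!is.null(g$re_cov)) g$re_cov <- matrix(unlist(g$re_cov), 2, 2)
      check_section_keys(g, growth_params, "natural_history.growth")
      x$growth <- do.call(growth_params, g)
    }
    if (!is.null(x$rupture)) {
      check_section_keys(x$rupture, rupture_params, "natural_history.rupture")
      x$rupture <- do.call(rupture_params, x$rupture)
    }
    x$life_table <- build_life_table(x$life_table)
    check_section_keys(x, natural_history_config, "natural_history")
    do.call(natural_history_config, x)
  },
  policy = function(x) {
    if (!is.null(x$surveillance_bands)) {
      x$surveillance_bands <- as.data.frame(lapply(x$surveillance_bands, unlist))
    }
    if (!is.null(x$invite_age) && is.character(x$invite_age)) {
      x$invite_age <- NA
    }
    check_section_keys(x, screening_policy, "policy")
    do.call(screening_policy, x)
  },
  econ = function(x) {
    if (!is.null(x$costs)) x$costs <- unlist(x$costs)
    if (!is.null(x$utilities)) {
      x$utilities <- as.data.frame(lapply(x$utilities, unlist))
    }
    check_section_keys(x, econ_config, "econ")
    do.call(econ_config, x)
  }
)

build_life_table <- function(x) {
  if (is.null(x)) return(make_life_table())
  if (is.character(x)) return(read_life_table(x))
  if (!is.null(x$file)) return(read_life_table(x$file))
  check_section_keys(x, make_life_table, "life_table")
  do.call(make_life_table, x)
}

check_section_keys <- function(x, fn, section) {
  unknown <- setdiff(names(x), names(formals(fn)))
  if (length(unknown)) {
    stop_config("unknown key(s) in section '%s': %s", section,
                paste(unknown, collapse = ", "))
  }
  invisible(x)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections `cohort`, `natural_history`,
#' `policy`, `econ`, `seeds` and `output_dir` (all optional; defaults are
#' applied and recorded). Every value is validated by the corresponding
#' constructor, so errors name the offending key and constraint; unknown
#' keys are rejected.
#'
#' @param path path to a YAML file.
#' @return A list of class `"run_config"` with elements `cohort`,
#'   `natural_history`, `policy`, `econ`, `seeds`, `output_dir`, plus the
#'   raw parsed YAML in `raw` and a character vector `user_keys` recording
#'   which top-level sections were user-supplied rather than defaulted.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file '%s' does not exist", path)
  ## keep single-letter keys like `n` as strings (YAML 1.1 would otherwise
  ## resolve them as booleans) while still converting genuine yes/no values
  handlers <- list(
    "bool#yes" = function(x) if (toupper(x) %in% c("TRUE", "YES", "ON")) TRUE else x,
    "bool#no" = function(x) if (toupper(x) %in% c("FALSE", "NO", "OFF")) FALSE else x)
  raw <- yaml::yaml.load_file(path, handlers = handlers)
  if (is.null(raw)) raw <- list()
  known <- c("cohort", "natural_history", "policy", "econ", "seeds",
             "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_config("unknown top-level key(s): %s", paste(unknown, collapse = ", "))
  }
  seeds <- raw$seeds %||% list(cohort = 1L, des = 2L, psa = 3L)
  seeds <- lapply(seeds, function(s) {
    check_number(s, "seeds"); as.integer(s)
  })
  out <- list(
    cohort = section_builders$cohort(raw$cohort %||% list()),
    natural_history = section_builders$natural_history(raw$natural_history %||% list()),
    policy = section_builders$policy(raw$policy %||% list()),
    econ = section_builders$econ(raw$econ %||% list()),
    seeds = seeds,
    output_dir = raw$output_dir %||% ".",
    raw = raw,
    user_keys = names(raw)
  )
  class(out) <- "run_config"
  out
}

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  user-supplied sections: %s\n",
              if (length(x$user_keys)) paste(x$user_keys, collapse = ", ")
              else "(none; all defaults)"))
  cat(sprintf("  cohort: n = %d, policy: %s invite %s, wtp = %g\n",
              x$cohort$n, x$policy$sex,
              if (is.na(x$policy$invite_age)) "none"
              else format(x$policy$invite_age), x$econ$wtp))
  invisible(x)
}

## Canonical hash of an R object: md5 of its deparsed representation.
object_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(x), tmp)
  unname(tools::md5sum(tmp))
}

#' Write stage outputs with a reproducibility manifest
#'
#' Serialises a named list of results (data frames as CSV, everything else
#' as JSON) into `output_dir` and writes `manifest.json` listing every
#' emitted file with its MD5 checksum, the package version, the seeds and a
#' hash of the configuration. Re-running a deterministic stage with the same
#' configuration and seeds reproduces the files and the manifest
#' byte-identically.
#'
#' @param results named list of stage outputs.
#' @param output_dir output directory (created if needed).
#' @param config optional configuration object hashed into the manifest.
#' @param seeds optional named seeds recorded in the manifest.
#' @param force overwrite existing files (otherwise a collision is an
#'   error).
#' @return The manifest (invisibly), a list.
#' @export
write_results <- function(results, output_dir, config = NULL, seeds = NULL,
                          force = FALSE) {
  stopifnot(is.list(results), !is.null(names(results)), all(nzchar(names(results))))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    fname <- if (is.data.frame(x)) paste0(nm, ".csv") else paste0(nm, ".json")
    fpath <- file.path(output_dir, fname)
    if (file.exists(fpath) && !force) {
      stop_config("output file '%s' already exists (use force = TRUE)", fpath)
    }
    if (is.data.frame(x)) {
      utils::write.csv(x, fpath, row.names = FALSE)
    } else {
      jsonlite::write_json(x, fpath, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    }
    files <- c(files, fname)
  }
  manifest <- list(
    package = "aaascreen",
    version = as.character(utils::packageVersion("aaascreen")),
    config_hash = if (is.null(config)) NA else object_hash(config),
    seeds = seeds,
    files = lapply(files, function(f) {
      list(name = f, md5 = unname(tools::md5sum(file.path(output_dir, f))))
    })
  )
  mpath <- file.path(output_dir, "manifest.json")
  if (file.exists(mpath) && !force) {
    stop_config("output file '%s' already exists (use force = TRUE)", mpath)
  }
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}
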