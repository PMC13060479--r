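# Configuration, serialization, and run directories.

# Write a data.frame as CSV with full double precision (17 significant
# digits round-trips a double exactly), header row, '.' decimal separator.
write_csv_full <- function(df, path) {
  fmt_col <- function(v) {
    if (is.double(v)) sprintf("%.17g", v) else as.character(v)
  }
  cols <- lapply(df, fmt_col)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

config_fields <- list(
  problem = "binh_korn", observations = NA_character_,
  T0 = 1, cooling_rate = 0.90, Tmin = 1e-3, n_iter = 50L, rank_cutoff = 8L,
  n_max = 5000L, step_scale = 0.05, max_evals = Inf,
  n_chains = 8L, seed = 1L, rank_filter = 1L,
  out_dir = NA_character_, ref_point = NULL)

#' Load and validate a run configuration
#'
#' Reads a flat JSON document of run settings, rejects unknown keys by name,
#' applies documented defaults, and validates the annealing-schedule
#' invariants before any computation (an invalid field is reported by its key,
#' e.g. \code{cooling_rate}).
#'
#' Recognised keys: \code{problem}, \code{observations} (CSV path, for the
#' cellfree problem), \code{T0}, \code{cooling_rate}, \code{Tmin},
#' \code{n_iter}, \code{rank_cutoff}, \code{n_max}, \code{step_scale},
#' \code{max_evals}, \code{n_chains}, \code{seed}, \code{rank_filter},
#' \code{out_dir}, \code{ref_point}.
#'
#' @param path Path to a JSON config file, or a named list of settings.
#' @return A list of class \code{"poets_config"} with all defaults resolved
#'   and a validated \code{schedule} component.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (is.list(path)) {
    path
  } else {
    stop("path must be a file path or a named list", call. = FALSE)
  }
  unknown <- setdiff(names(raw), names(config_fields))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- config_fields
  cfg[names(raw)] <- raw
  if (identical(cfg$max_evals, "Inf")) cfg$max_evals <- Inf
  check_count <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1) {
      stop("config key '", key, "' must be a positive integer", call. = FALSE)
    }
    as.integer(v)
  }
  cfg$n_chains <- check_count("n_chains")
  cfg$seed <- as.integer(cfg$seed)
  cfg$rank_filter <- as.integer(cfg$rank_filter)
  if (is.na(cfg$rank_filter) || cfg$rank_filter < 0L) {
    stop("config key 'rank_filter' must be >= 0", call. = FALSE)
  }
  sched <- tryCatch(
    poets_schedule(T0 = cfg$T0, cooling_rate = cfg$cooling_rate,
                   Tmin = cfg$Tmin, n_iter = cfg$n_iter,
                   rank_cutoff = cfg$rank_cutoff, n_max = cfg$n_max,
                   step_scale = cfg$step_scale, max_evals = cfg$max_evals),
    error = function(e) stop("config: ", conditionMessage(e), call. = FALSE))
  cfg$schedule <- sched
  class(cfg) <- "poets_config"
  cfg
}

effective_config <- function(cfg) {
  out <- unclass(cfg)
  out$schedule <- NULL
  out$out_dir <- NULL  # implied by the run directory; keeps runs comparable
  out$max_evals <- if (is.infinite(out$max_evals)) "Inf" else out$max_evals
  out[!vapply(out, function(v) is.null(v) ||
                (length(v) == 1L && is.na(v)), logical(1))]
}

#' Write a fitted ensemble to a run directory
#'
#' Serializes a \code{\link{poets}} result as plain-text artifacts: the
#' merged archive as a flat CSV (columns \code{chain_id},
#' \code{insertion_index}, \code{rank}, then the parameter and objective
#' columns; full double precision so re-reading and re-ranking reproduces the
#' stored rank column exactly), a JSON metadata sidecar (column names,
#' dimensions, capacity, cutoff, seed, schedule, problem name, evaluation
#' count), and one convergence-trace CSV per chain.
#'
#' @param result A fitted \code{\link{poets}} object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written paths.
#' @export
write_ensemble <- function(result, dir) {
  stopifnot(inherits(result, "poets"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2L) != 0L) {
    stop("cannot write to directory '", dir, "'", call. = FALSE)
  }
  a <- result$archive
  archive_path <- file.path(dir, "archive.csv")
  write_csv_full(as.data.frame(a), archive_path)
  meta <- list(
    package = "poets",
    version = as.character(utils::packageVersion("poets")),
    problem = result$problem$name,
    par_names = colnames(a$params),
    obj_names = colnames(a$objectives),
    d = ncol(a$params), m = ncol(a$objectives),
    n_max = a$n_max, rank_cutoff = a$rank_cutoff,
    n_chains = result$n_chains, seed = result$seed,
    rank_filter = result$rank_filter,
    n_evals = result$n_evals,
    scale = result$problem$scale,
    ref_point = result$problem$ref_point,
    schedule = unclass(result$schedule)[c("T0", "cooling_rate", "Tmin",
                                          "n_iter", "rank_cutoff", "n_max",
                                          "step_scale", "acceptance")])
  meta_path <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  trace_paths <- character(0)
  for (i in seq_along(result$traces)) {
    tr <- result$traces[[i]]
    if (is.null(tr)) next
    p <- file.path(dir, sprintf("trace-chain-%d.csv", i))
    write_csv_full(tr, p)
    trace_paths <- c(trace_paths, p)
  }
  invisible(list(archive = archive_path, metadata = meta_path,
                 traces = trace_paths))
}

#' Read an ensemble run directory
#'
#' Reconstructs the archive (and metadata) written by
#' \code{\link{write_ensemble}}.
#'
#' @param dir Run directory.
#' @return A list with \code{archive} (a \code{\link{poets_archive}} carrying
#'   the stored ranks) and \code{metadata}.
#' @export
read_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  tab <- read.csv(file.path(dir, "archive.csv"))
  pn <- meta$par_names
  on <- meta$obj_names
  P <- as.matrix(tab[, pn, drop = FALSE])
  F <- as.matrix(tab[, on, drop = FALSE])
  archive <- poets_archive(P, F, n_max = meta$n_max,
                           rank_cutoff = meta$rank_cutoff,
                           chain_id = tab$chain_id,
                           insertion = tab$insertion_index,
                           rank = tab$rank)
  colnames(archive$params) <- pn
  colnames(archive$objectives) <- on
  list(archive = archive, metadata = meta)
}
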