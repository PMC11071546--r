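#' Posterior draws container
#'
#' Bundles an s x p matrix of posterior parameter draws with parameter names
#' and the provenance of the sample (MCMC or a variational approximation).
#' Every downstream computation in the package consumes draws through this
#' container; no function re-reads files.
#'
#' @param draws numeric matrix, one row per draw, one column per parameter.
#' @param param_names character vector of length `ncol(draws)`; defaults to the
#'   column names of `draws`.
#' @param source `"mcmc"` or `"variational"`; variational draws additionally
#'   support the density-corrected weights of
#'   [variational_corrected_log_weights()].
#' @return An object of class `posterior_draws` with elements `draws`,
#'   `param_names` and `source`.
#' @seealso [read_draws()], [write_draws()]
#' @export
posterior_draws <- function(draws, param_names = colnames(draws),
                            source = c("mcmc", "variational")) {
  source <- match.arg(source)
  draws <- as.matrix(draws)
  if (!is.numeric(draws)) stop("draws must be numeric", call. = FALSE)
  storage.mode(draws) <- "double"
  if (nrow(draws) < 2L) {
    stop("at least 2 draws required (s >= 2), got ", nrow(draws), call. = FALSE)
  }
  if (ncol(draws) < 1L) stop("at least one parameter required (p >= 1)", call. = FALSE)
  bad <- which(!is.finite(draws), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite draw value at row %d, column %d",
                 bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  }
  if (is.null(param_names)) param_names <- paste0("theta", seq_len(ncol(draws)))
  param_names <- as.character(param_names)
  if (length(param_names) != ncol(draws)) {
    stop("param_names length must equal the number of parameters", call. = FALSE)
  }
  if (anyDuplicated(param_names)) {
    stop("param_names must be unique; duplicated: ",
         paste(unique(param_names[duplicated(param_names)]), collapse = ", "),
         call. = FALSE)
  }
  colnames(draws) <- param_names
  structure(list(draws = draws, param_names = param_names, source = source),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d draws x %d parameters (%s)\n",
              nrow(x$draws), ncol(x$draws), x$source))
  invisible(x)
}

#' @export
dim.posterior_draws <- function(x) dim(x$draws)

#' Binary-classification dataset container
#'
#' Holds covariate rows paired with 0/1 labels; row `i` is the observation
#' left out when forming the `i`-th LOO fold.
#'
#' @param X numeric matrix of covariates, one row per observation.
#' @param y integer/numeric vector of labels in `{0, 1}`.
#' @return An object of class `loo_dataset` with elements `X`, `y` and `n`.
#' @export
loo_dataset <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed", call. = FALSE)
  if (!all(y %in% c(0, 1))) {
    stop("labels must be 0 or 1; offending values: ",
         paste(unique(y[!y %in% c(0, 1)]), collapse = ", "), call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (nrow(X) < 2L) stop("n >= 2 required", call. = FALSE)
  if (any(!is.finite(X))) stop("covariates must be finite", call. = FALSE)
  structure(list(X = X, y = y, n = nrow(X)), class = "loo_dataset")
}

#' @export
print.loo_dataset <- function(x, ...) {
  cat(sprintf("<loo_dataset> n = %d observations, %d covariates, %d positive labels\n",
              x$n, ncol(x$X), sum(x$y)))
  invisible(x)
}

#' Run configuration
#'
#' Settings shared by the adaptive LOO pipeline: the Pareto tail-shape
#' threshold above which adaptation is triggered, the grid of relative step
#' sizes scanned per transformation, the order in which transformations are
#' attempted, and a global seed from which all per-observation child seeds are
#' derived.
#'
#' @param khat_threshold tail-shape diagnostic threshold; adaptation is
#'   attempted for observations whose smoothed-weight k-hat exceeds it.
#' @param hbar_grid decreasing grid of relative step sizes in (0, 1]; the
#'   default is `4^-(0:10)`.
#' @param transform_order character vector of method labels drawn from
#'   `c("PMM1","PMM2","MM1","MM2","KL","Var","LL")`, attempted in order.
#' @param seed global integer seed; stochastic operations derive child seeds
#'   from (seed, observation index, method label).
#' @param tail_fraction_rule label recording the tail-size rule in use (the
#'   implemented rule is `M = ceiling(min(0.2 s, 3 sqrt(s)))`).
#' @param search `"first_success"` stops at the first (method, h-bar) pair that
#'   brings k-hat under threshold; `"exhaustive"` scans everything and reports
#'   the global minimizer.
#' @param use_best_khat if `TRUE`, LOO metrics for adapted observations use the
#'   weights with the smallest k-hat across all scanned pairs rather than the
#'   winner's weights.
#' @return An object of class `run_config`.
#' @export
run_config <- function(khat_threshold = 0.7,
                       hbar_grid = 4^-(0:10),
                       transform_order = c("PMM1", "PMM2", "KL", "Var", "LL"),
                       seed = 1L,
                       tail_fraction_rule = "psis",
                       search = c("first_success", "exhaustive"),
                       use_best_khat = FALSE) {
  search <- match.arg(search)
  if (!is.numeric(khat_threshold) || khat_threshold <= 0) {
    stop("khat_threshold must be > 0", call. = FALSE)
  }
  hbar_grid <- as.numeric(hbar_grid)
  if (any(hbar_grid <= 0 | hbar_grid > 1)) {
    stop("all hbar_grid values must lie in (0, 1]", call. = FALSE)
  }
  known <- c("PMM1", "PMM2", "MM1", "MM2", "KL", "Var", "LL")
  bad <- setdiff(transform_order, known)
  if (length(bad)) stop("unknown transformation label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(khat_threshold = khat_threshold,
                 hbar_grid = hbar_grid,
                 transform_order = transform_order,
                 seed = as.integer(seed),
                 tail_fraction_rule = tail_fraction_rule,
                 search = search,
                 use_best_khat = isTRUE(use_best_khat)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  khat_threshold:", x$khat_threshold, "\n")
  cat("  hbar_grid:", paste(signif(x$hbar_grid, 4), collapse = " "), "\n")
  cat("  transform_order:", paste(x$transform_order, collapse = " > "), "\n")
  cat("  seed:", x$seed, " search:", x$search, "\n")
  invisible(x)
}

# deterministic child seed below 2^31, from (global seed, obs index, label)
child_seed <- function(seed, i = 0L, label = "") {
  h <- as.double(seed) %% 2147483647
  h <- (h * 48271 + as.double(i) * 7919) %% 2147483647
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Read posterior draws from a headered CSV table
#'
#' One row per draw, one column per parameter, header row of parameter names
#' (the plain export format of most probabilistic programming frameworks after
#' column selection).
#'
#' @param path file path of the CSV table.
#' @param names optional character vector: restrict and reorder columns.
#' @param source passed to [posterior_draws()].
#' @return A [posterior_draws()] object.
#' @export
read_draws <- function(path, names = NULL, source = "mcmc") {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(names)) {
    missing_cols <- setdiff(names, colnames(tab))
    if (length(missing_cols)) {
      stop("draws table is missing column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    tab <- tab[, names, drop = FALSE]
  }
  non_num <- !vapply(tab, is.numeric, logical(1))
  if (any(non_num)) {
    stop("non-numeric draws column(s): ",
         paste(colnames(tab)[non_num], collapse = ", "), call. = FALSE)
  }
  posterior_draws(as.matrix(tab), param_names = colnames(tab), source = source)
}

#' Write posterior draws to CSV at full double precision
#'
#' @param draws a [posterior_draws()] object.
#' @param path output file path.
#' @return `path`, invisibly. Reading the file back with [read_draws()]
#'   reproduces the matrix bit-exactly.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  m <- draws$draws
  txt <- apply(m, 2L, function(col) sprintf("%.17g", col))
  utils::write.table(rbind(draws$param_names, txt), file = path, sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a classification dataset from CSV
#'
#' @param path file path; a headered CSV with one row per observation.
#' @param label_column name of the 0/1 label column; all remaining columns,
#'   in file order, become covariates.
#' @return A [loo_dataset()] object.
#' @export
read_dataset <- function(path, label_column = "y") {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (nrow(tab) < 2L) stop("n >= 2 required", call. = FALSE)
  if (!label_column %in% colnames(tab)) {
    stop("label column '", label_column, "' not found", call. = FALSE)
  }
  y <- tab[[label_column]]
  X <- as.matrix(tab[, setdiff(colnames(tab), label_column), drop = FALSE])
  loo_dataset(X, y)
}

#' Write a classification dataset to CSV at full double precision
#'
#' @param data a [loo_dataset()] object.
#' @param path output file path.
#' @param label_column name used for the label column.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path, label_column = "y") {
  stopifnot(inherits(data, "loo_dataset"))
  xn <- colnames(data$X)
  if (is.null(xn)) xn <- paste0("x", seq_len(ncol(data$X)))
  txt <- apply(data$X, 2L, function(col) sprintf("%.17g", col))
  out <- cbind(txt, sprintf("%d", as.integer(data$y)))
  utils::write.table(rbind(c(xn, label_column), out), file = path, sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a run configuration from a YAML key:value file
#'
#' Recognized keys match the arguments of [run_config()]; unknown keys are an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()] object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(run_config, vals)
}

#' Write a LOO report to JSON
#'
#' Serializes the per-observation records (raw and per-method k-hat, winning
#' method, LOO predictive probability, elpd), the global metrics (LOO-IC,
#' AUROC, AUPRC, failure count) and the run configuration used, at full
#' numeric precision.
#'
#' @param report a `loo_report` as returned by [run_loo()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "loo_report"))
  doc <- list(
    per_obs = lapply(report$per_obs, function(r) {
      list(index = r$index,
           khat_raw = r$khat_raw,
           khat_by_method = as.list(r$khat_by_method),
           winner = r$winner,
           hbar = r$hbar,
           p_loo = r$p_loo,
           elpd_i = r$elpd_i)
    }),
    loo_ic = report$loo_ic,
    n_failed = report$n_failed,
    auroc = report$auroc,
    auprc = report$auprc,
    config = unclass(report$config)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a LOO report back from JSON
#'
#' @param path file written by [write_report()].
#' @return A `loo_report` object (without the weight vectors, which are not
#'   serialized).
#' @export
read_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  per_obs <- lapply(doc$per_obs, function(r) {
    list(index = as.integer(r$index),
         khat_raw = num_or_na(r$khat_raw),
         khat_by_method = vapply(r$khat_by_method, num_or_na, 0.0),
         winner = r$winner,
         hbar = num_or_na(r$hbar),
         p_loo = num_or_na(r$p_loo),
         elpd_i = num_or_na(r$elpd_i))
  })
  cfg <- doc$config
  config <- run_config(khat_threshold = cfg$khat_threshold,
                       hbar_grid = unlist(cfg$hbar_grid),
                       transform_order = unlist(cfg$transform_order),
                       seed = cfg$seed,
                       tail_fraction_rule = cfg$tail_fraction_rule,
                       search = cfg$search,
                       use_best_khat = isTRUE(cfg$use_best_khat))
  structure(list(per_obs = per_obs,
                 loo_ic = num_or_na(doc$loo_ic),
                 n_failed = as.integer(doc$n_failed),
                 auroc = num_or_na(doc$auroc),
                 auprc = num_or_na(doc$auprc),
                 config = config),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  n <- length(x$per_obs)
  cat(sprintf("<loo_report> %d observations, %d adaptation failure(s)\n",
              n, x$n_failed))
  cat(sprintf("  LOO-IC: %.3f", x$loo_ic))
  if (is.finite(x$auroc)) cat(sprintf("   AUROC: %.3f   AUPRC: %.3f", x$auroc, x$auprc))
  cat("\n")
  kh <- vapply(x$per_obs, function(r) r$khat_raw, 0.0)
  cat(sprintf("  raw k-hat > %.2f for %d observation(s)\n",
              x$config$khat_threshold, sum(kh > x$config$khat_threshold, na.rm = TRUE)))
  invisible(x)
}
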