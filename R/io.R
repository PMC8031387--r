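# Delimited-text readers/writers and fixture generation.  Plain-text formats
# only: CSV/TSV matrices with a header row and samples in rows, JSON sidecars
# for structured results.

guess_sep <- function(path) {
  switch(tolower(tools::file_ext(path)),
         csv = ",", tsv = "\t", tab = "\t", txt = "\t", "\t")
}

#' Read a regression dataset from delimited text
#'
#' Expects samples in rows and a header line; one column is the response, the
#' rest form the design matrix.  Every cell must be numeric -- the first
#' offending cell is reported with its (row, column) coordinates.
#'
#' @param path File path (`.csv` implies comma, otherwise tab; override with
#'   `sep`).
#' @param response Response column, by name or index (default 1).
#' @param sep Field delimiter (optional).
#' @param header Does the file have a header row? Default `TRUE`.
#' @return List with `X` (numeric matrix), `y`, `response_name`, `n`, `p`.
#'   Unprepared: pass through [prepare_data()] before fitting.
#' @export
read_dataset <- function(path, response = 1L, sep = NULL, header = TRUE) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  sep <- sep %||% guess_sep(path)
  df <- utils::read.table(path, sep = sep, header = header,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (nrow(df) < 2L) stop_input("dataset needs at least 2 rows (got %d)", nrow(df))
  if (is.character(response)) {
    ri <- match(response, colnames(df))
    if (is.na(ri)) stop_input("response column '%s' not found", response)
  } else {
    ri <- as.integer(response)
    if (ri < 1L || ri > ncol(df)) {
      stop_input("response index %d out of range 1..%d", ri, ncol(df))
    }
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop_input("non-numeric value at row %d, column %d ('%s')",
                   bad[1L], j, as.character(col[bad[1L]]))
      }
      df[[j]] <- num
    }
  }
  y <- df[[ri]]
  X <- as.matrix(df[, -ri, drop = FALSE])
  list(X = X, y = y, response_name = colnames(df)[ri],
       n = nrow(X), p = ncol(X))
}

#' Write a coefficient report
#'
#' Two-column TSV (term, coefficient) preceded by `#`-prefixed metadata
#' header lines.
#'
#' @param beta Named (or unnamed) coefficient vector.
#' @param path Output path.
#' @param meta Named list of metadata values written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(beta, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(meta)) {
    writeLines(sprintf("# %s: %s", key, format(meta[[key]])), con)
  }
  writeLines("term\tcoefficient", con)
  nm <- names(beta) %||% paste0("x", seq_along(beta))
  writeLines(paste(nm, format(unname(beta), digits = 12, trim = TRUE),
                   sep = "\t"), con)
  invisible(path)
}

fixture_settings <- list(
  tiny_lowdim  = list(n = 40L, p = 8L,  gamma = 0.5, cs = 0),
  tiny_highdim = list(n = 30L, p = 60L, gamma = 0.5, cs = 0),
  contaminated = list(n = 50L, p = 10L, gamma = 0.5, cs = 20)
)

#' Write a small simulated dataset to disk
#'
#' Generates one of three desk-scale fixtures through the simulation module
#' and writes it as a TSV (column `y` followed by the covariates) plus a JSON
#' truth sidecar holding the true coefficients, the per-sample contamination
#' flags and the generator settings.  Output bytes are a deterministic
#' function of `kind` and `seed`.
#'
#' Kinds: `tiny_lowdim` (n = 40, p = 8), `tiny_highdim` (n = 30, p = 60),
#' `contaminated` (n = 50, p = 10, CS = 20 percent).
#'
#' @param kind Fixture kind.
#' @param dir Output directory (default [tempdir()]).
#' @param seed RNG seed (default 1).
#' @return List with `path`, `truth_path`, `n`, `p`.
#' @export
make_fixture <- function(kind = c("tiny_lowdim", "tiny_highdim", "contaminated"),
                         dir = tempdir(), seed = 1L) {
  kind <- match.arg(kind)
  st <- fixture_settings[[kind]]
  cfg <- sim_config(st$n, st$p, gamma = st$gamma, cs_percent = st$cs,
                    M = 1L, seed = seed)
  ss <- derive_seeds(cfg$seed, 3L)
  X <- gen_design(cfg$n, cfg$p, cfg$gamma, seed = ss[1])
  beta <- gen_beta(cfg$p, cfg$sparsity, seed = ss[2])
  eps <- gen_errors(cfg$n, cfg$cs_percent, cfg$sigma_sq, seed = ss[3])
  y <- drop(X %*% beta) + eps

  path <- file.path(dir, paste0(kind, ".tsv"))
  df <- data.frame(y = y, X, check.names = FALSE)
  con <- file(path, "w")
  writeLines(paste(colnames(df), collapse = "\t"), con)
  writeLines(apply(df, 1L, function(r) {
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t")
  }), con)
  close(con)

  truth_path <- file.path(dir, paste0(kind, "_truth.json"))
  truth <- list(
    kind = kind, seed = cfg$seed,
    beta = beta,
    contaminated = c(rep(FALSE, cfg$h), rep(TRUE, cfg$n - cfg$h)),
    config = list(n = cfg$n, p = cfg$p, gamma = cfg$gamma,
                  sparsity = cfg$sparsity, cs_percent = cfg$cs_percent,
                  sigma_sq = cfg$sigma_sq)
  )
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  list(path = path, truth_path = truth_path, n = cfg$n, p = cfg$p)
}
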