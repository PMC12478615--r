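#' File I/O: datasets, model specs, draws, run manifests, CLI
#'
#' Interchange formats are plain text: headered CSV (UTF-8, '.' decimal)
#' for rectangular data and draw tables, JSON for the model spec and the
#' run manifest. Draw tables are wide, one row per retained draw, with
#' systematic column names (`W[p]`, `A2[k,r]`, `gamma[q,j]`, ...).
#'
#' @name era-io
NULL

era_files <- c(X = "X.csv", Cov = "Cov.csv", M = "M.csv",
               Ycont = "Ycont.csv", Yord = "Yord.csv")

#' Write a dataset as CSV files
#'
#' @param data An [era_data()].
#' @param dir Output directory (created if absent); one CSV per non-empty
#'   matrix (`X.csv`, `Cov.csv`, `M.csv`, `Ycont.csv`, `Yord.csv`).
#' @return Invisibly the vector of files written.
#' @export
write_era_dataset <- function(data, dir) {
  stopifnot(inherits(data, "era_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  for (nm in names(era_files)) {
    A <- data[[nm]]
    if (!ncol(A)) next
    colnames(A) <- sprintf("%s%d", tolower(nm), seq_len(ncol(A)))
    path <- file.path(dir, era_files[[nm]])
    utils::write.csv(as.data.frame(A), path, row.names = FALSE)
    written <- c(written, path)
  }
  invisible(written)
}

#' Read a dataset from CSV files
#'
#' Reads the CSVs written by [write_era_dataset()] and validates against
#' the spec. Missing values, non-numeric cells and absent required files
#' raise named errors; ordinal columns are parsed as integers.
#'
#' @param dir Directory containing the CSV files.
#' @param spec An [era_spec()].
#' @return A validated [era_data()].
#' @export
read_era_dataset <- function(dir, spec) {
  get <- function(nm, need) {
    path <- file.path(dir, era_files[[nm]])
    if (!need) return(NULL)
    if (!file.exists(path))
      stop(sprintf("required file %s is missing", path))
    df <- utils::read.csv(path)
    for (cn in names(df)) {
      if (!is.numeric(df[[cn]]))
        stop(sprintf("%s: column %s is not numeric", era_files[[nm]], cn))
      if (anyNA(df[[cn]]))
        stop(sprintf("%s: missing value in column %s (row %d)",
                     era_files[[nm]], cn, which(is.na(df[[cn]]))[1L]))
    }
    as.matrix(df)
  }
  Yord <- get("Yord", spec$Q - spec$T > 0)
  if (!is.null(Yord)) storage.mode(Yord) <- "integer"
  data <- era_data(X = get("X", TRUE), Cov = get("Cov", spec$C > 0),
                   M = get("M", spec$R > 0),
                   Ycont = get("Ycont", spec$T > 0), Yord = Yord)
  validate_era(spec, data)
  data
}

#' Serialize / deserialize a model spec as JSON
#'
#' Round-trip faithful: `spec_from_json(spec_to_json(s))` is identical to
#' `s`.
#'
#' @param spec An [era_spec()].
#' @param path File path; for `spec_to_json`, `NULL` returns the JSON
#'   string instead of writing.
#' @return `spec_to_json`: the path (or JSON string); `spec_from_json`:
#'   an [era_spec()].
#' @export
spec_to_json <- function(spec, path = NULL) {
  x <- list(blocks = spec$blocks, n_covariates = spec$C,
            n_mediators = spec$R, n_continuous = spec$T,
            n_categories = spec$categories)
  js <- jsonlite::toJSON(x, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname spec_to_json
#' @param json JSON string or file path produced by [spec_to_json()].
#' @export
spec_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  era_spec(blocks = as.integer(x$blocks),
           n_covariates = as.integer(x$n_covariates),
           n_mediators = as.integer(x$n_mediators),
           n_continuous = as.integer(x$n_continuous),
           n_categories = as.integer(x$n_categories))
}

# Flatten era_draws to a wide numeric matrix with systematic column names.
draws_to_table <- function(d) {
  if (inherits(d, "era_fit")) d <- d$draws
  S <- nrow(d$w)
  pieces <- list()
  add <- function(x, names) {
    x <- matrix(x, nrow = S)
    colnames(x) <- names
    pieces[[length(pieces) + 1L]] <<- x
  }
  add(d$w, idx_names("W", ncol(d$w)))
  add(d$a0, idx_names("a0", ncol(d$a0)))
  add(d$A3, idx_names("A3", dim(d$A3)[2L], dim(d$A3)[3L]))
  if (length(d$A4)) {
    add(d$a1, idx_names("a1", ncol(d$a1)))
    add(d$A2, idx_names("A2", dim(d$A2)[2L], dim(d$A2)[3L]))
    add(d$A4, idx_names("A4", dim(d$A4)[2L], dim(d$A4)[3L]))
    add(d$SigmaM, idx_names("SigmaM", dim(d$SigmaM)[2L],
                            dim(d$SigmaM)[3L]))
    add(d$nu_M, "nu_M")
  }
  add(d$SigmaY, idx_names("SigmaY", dim(d$SigmaY)[2L], dim(d$SigmaY)[3L]))
  add(d$nu_C, "nu_C")
  for (j in seq_along(d$cut))
    add(d$cut[[j]], sprintf("gamma[%d,%d]", j, seq_len(ncol(d$cut[[j]]))))
  do.call(cbind, pieces)
}

#' Write retained draws to a CSV table
#'
#' One row per retained draw, systematic column names. Values round-trip
#' losslessly through [read_era_draws()] (full double precision).
#'
#' @param draws An `"era_draws"` or `"era_fit"`.
#' @param path Output CSV path.
#' @return Invisibly `path`.
#' @export
write_era_draws <- function(draws, path) {
  tab <- draws_to_table(draws)
  chr <- matrix(sprintf("%.17g", tab), nrow = nrow(tab))  # lossless doubles
  lines <- c(paste(sprintf('"%s"', colnames(tab)), collapse = ","),
             apply(chr, 1L, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a draw table written by [write_era_draws()]
#'
#' @param path CSV path.
#' @param spec The [era_spec()] the fit used.
#' @return An `"era_draws"` object (without latent matrices).
#' @export
read_era_draws <- function(path, spec) {
  tab <- as.matrix(utils::read.csv(path, check.names = FALSE))
  S <- nrow(tab)
  CK <- spec$C + spec$K
  grab <- function(names, dims) {
    x <- tab[, names, drop = FALSE]
    array(x, c(S, dims))
  }
  has_med <- any(grepl("^A4\\[", colnames(tab)))
  R <- if (has_med) spec$R else 0L
  n_ord <- spec$Q - spec$T
  structure(list(
    w = grab(idx_names("W", spec$P), spec$P),
    blocks = spec$blocks,
    a0 = grab(idx_names("a0", spec$Q), spec$Q),
    A3 = grab(idx_names("A3", CK, spec$Q), c(CK, spec$Q)),
    A4 = if (R) grab(idx_names("A4", R, spec$Q), c(R, spec$Q))
      else array(NA_real_, c(S, 0L, spec$Q)),
    a1 = if (R) grab(idx_names("a1", R), R)
      else matrix(NA_real_, S, 0L),
    A2 = if (R) grab(idx_names("A2", CK, R), c(CK, R))
      else array(NA_real_, c(S, CK, 0L)),
    SigmaM = if (R) grab(idx_names("SigmaM", R, R), c(R, R))
      else array(NA_real_, c(S, 0L, 0L)),
    nu_M = if (R) as.numeric(tab[, "nu_M"]) else rep(NA_real_, S),
    SigmaY = grab(idx_names("SigmaY", spec$Q, spec$Q),
                  c(spec$Q, spec$Q)),
    nu_C = as.numeric(tab[, "nu_C"]),
    cut = lapply(seq_len(n_ord), function(j) {
      nm <- sprintf("gamma[%d,%d]", j,
                    seq_len(spec$categories[j] - 1L))
      matrix(tab[, nm], S, length(nm))
    }),
    Z = NULL, n_continuous = spec$T, categories = spec$categories,
    identified = FALSE), class = "era_draws")
}

#' Write a run manifest as JSON
#'
#' Settings echo, seed, runtime, Metropolis acceptance rates and package
#' version, written next to fit outputs for reproducibility audits.
#'
#' @param fit An `"era_fit"`.
#' @param path Output JSON path.
#' @return Invisibly `path`.
#' @export
write_manifest <- function(fit, path) {
  man <- list(
    package = "bera",
    version = as.character(utils::packageVersion("bera")),
    settings = fit$control[c("n_iter", "burn_in", "thin", "seed",
                             "expand", "init")],
    include_mediators = fit$include_mediators,
    runtime_sec = fit$runtime,
    acceptance = fit$accept)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Command-line umbrella
#'
#' Subcommands: `simulate --n N --seed S --out DIR`,
#' `fit --data DIR --spec spec.json --iters I --burnin B --thin T --seed S
#' --out DIR [--no-mediators]`, `summarize --draws draws.csv --spec
#' spec.json --level L --out file.csv [--odds-ratio]`, `diagnose --draws
#' draws.csv --spec spec.json --param NAME`. Designed to be driven from an
#' `Rscript` wrapper (see `inst/scripts/bera`).
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly `NULL`; called for its file side effects.
#' @export
era_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: bera <simulate|fit|summarize|diagnose> ...")
  cmd <- args[[1L]]
  opts <- parse_cli_opts(args[-1L])
  switch(cmd,
    simulate = {
      sc <- default_scenario(as.integer(opts$n %||% 300),
                             seed = as.integer(opts$seed %||% 1))
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      write_era_dataset(sc$data, opts$out)
      spec_to_json(sc$spec, file.path(opts$out, "spec.json"))
      truth <- sc$truth
      truth$cutoffs <- lapply(truth$cutoffs, as.numeric)
      jsonlite::write_json(unclass(truth),
                           file.path(opts$out, "truth.json"),
                           auto_unbox = FALSE, digits = NA)
      message("wrote scenario to ", opts$out)
    },
    fit = {
      spec <- spec_from_json(opts$spec)
      data <- read_era_dataset(opts$data, spec)
      ctrl <- era_control(n_iter = as.integer(opts$iters %||% 30000),
                          burn_in = as.integer(opts$burnin %||% 2000),
                          thin = as.integer(opts$thin %||% 5),
                          seed = as.integer(opts$seed %||% 1),
                          store_latent = FALSE)
      fit <- era_fit(data, spec, control = ctrl,
                     include_mediators = is.null(opts[["no-mediators"]]))
      dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
      write_era_draws(fit, file.path(opts$out, "draws.csv"))
      write_manifest(fit, file.path(opts$out, "manifest.json"))
      message("wrote draws + manifest to ", opts$out)
    },
    summarize = {
      spec <- spec_from_json(opts$spec)
      draws <- read_era_draws(opts$draws, spec)
      eff <- indirect_effects(draws)
      tab <- summarize_effects(eff, level = as.numeric(opts$level %||% 0.95),
                               as_odds_ratio = !is.null(opts[["odds-ratio"]]))
      utils::write.csv(tab, opts$out, row.names = FALSE)
      message("wrote effect summaries to ", opts$out)
    },
    diagnose = {
      spec <- spec_from_json(opts$spec)
      draws <- read_era_draws(opts$draws, spec)
      dg <- ess_geweke(draws, opts$param)
      cat(sprintf("%s: ESS = %.1f, Geweke z = %.3f\n", opts$param,
                  dg$ess, dg$geweke_z))
    },
    stop(sprintf("unknown subcommand '%s'", cmd)))
  invisible(NULL)
}

# --key value / --flag parser.
parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a))
    key <- substring(a, 3L)
    if (i < length(args) && !startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    } else {
      opts[[key]] <- TRUE
      i <- i + 1L
    }
  }
  opts
}
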