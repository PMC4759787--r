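# Flat-file parameter and observation I/O. Parameters travel as one flat
# YAML/JSON mapping with fixed keys and units (hours, ug/ml, MBq/ug);
# observations as tidy CSV with columns time_h, chi1, chi2 and optional
# tat0, R, chi1_bar.

PARAM_KEYS <- list(
  rates = paste0("k", 1:6),
  ext = c("k7", "k8", "tat0", "k9", "kappa", "R"),
  constants = c("Ymax", "Zmax", "Zstar", "dsb_per_gy")
)

#' Read and write parameter files
#'
#' Parameters are stored as a flat YAML or JSON mapping (chosen by file
#' extension) with keys `k1..k9`, `kappa`, `tat0`, `R`, `Ymax`, `Zmax`,
#' `Zstar`, `dsb_per_gy`. Unknown keys are rejected. Missing assumed
#' constants are filled with the defaults (300 / 1000 / 200 / 40) with a
#' notice. The round trip `write_params(read_params(p))` is lossless.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_params()`: a list with elements `rates` ([dsb_rates()]),
#'   `ext` ([ext_rates()] or `NULL` when no extension key is present) and
#'   `constants` ([assumed_constants()]).
#' @export
read_params <- function(path) {
  x <- switch(tools::file_ext(tolower(path)),
              yaml = , yml = yaml::read_yaml(path),
              json = jsonlite::fromJSON(path),
              stop("parameter files must be .yaml/.yml or .json",
                   call. = FALSE))
  x <- lapply(x, as.numeric)
  known <- unlist(PARAM_KEYS)
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  missing_rates <- setdiff(PARAM_KEYS$rates, names(x))
  if (length(missing_rates))
    stop("missing rate constant(s): ", paste(missing_rates, collapse = ", "),
         call. = FALSE)
  for (kk in names(x))
    if (!is.finite(x[[kk]]) || x[[kk]] < 0)
      stop(sprintf("parameter '%s' must be finite and >= 0", kk),
           call. = FALSE)
  rates <- do.call(dsb_rates, x[PARAM_KEYS$rates])
  ext <- NULL
  if (any(PARAM_KEYS$ext %in% names(x)))
    ext <- do.call(ext_rates, x[intersect(PARAM_KEYS$ext, names(x))])
  filled <- setdiff(PARAM_KEYS$constants, names(x))
  if (length(filled))
    message("using default values for: ", paste(filled, collapse = ", "))
  constants <- do.call(assumed_constants,
                       x[intersect(PARAM_KEYS$constants, names(x))])
  list(rates = rates, ext = ext, constants = constants)
}

#' @rdname read_params
#' @param rates a [dsb_rates()] object (or the list returned by
#'   `read_params()`).
#' @param ext optional [ext_rates()].
#' @param constants optional [assumed_constants()].
#' @export
write_params <- function(rates, path, ext = NULL, constants = NULL) {
  if (is.list(rates) && !is.null(rates$rates)) {
    ext <- rates$ext
    constants <- rates$constants
    rates <- rates$rates
  }
  x <- as.list(setNames(as.numeric(rates), paste0("k", 1:6)))
  if (!is.null(ext))
    x <- c(x, as.list(setNames(as.numeric(ext), names(unclass(ext)))))
  if (!is.null(constants))
    x <- c(x, as.list(setNames(as.numeric(constants),
                               names(unclass(constants)))))
  switch(tools::file_ext(tolower(path)),
         yaml = , yml = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE,
                                     digits = NA),
         stop("parameter files must be .yaml/.yml or .json", call. = FALSE))
  invisible(path)
}

#' Read and write observation CSV files
#'
#' Observations are tidy CSV with header `time_h, chi1, chi2` and optional
#' `chi1_bar`, `tat0`, `R` columns (decimal point, UTF-8). Missing values
#' are allowed and preserved. When the file mixes several conditions
#' (distinct `tat0`/`R` combinations), `read_observations()` returns one
#' `dsb_obs` per condition, so a concentration panel file loads directly
#' into the shape wanted by [fit_antibody_grouping()].
#'
#' @param path CSV file path.
#' @return A `dsb_obs`, or a named list of them for a multi-condition file.
#' @export
read_observations <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = TRUE, fileEncoding = "UTF-8")
  need <- c("time_h", "chi1", "chi2")
  if (!all(need %in% names(raw)))
    stop("observation CSV must have columns time_h, chi1, chi2",
         call. = FALSE)
  numcols <- intersect(c(need, "chi1_bar", "tat0", "R"), names(raw))
  for (cc in numcols) {
    v <- trimws(raw[[cc]])
    v[v == ""] <- NA
    conv <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(conv))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   v[bad[1]], bad[1], cc), call. = FALSE)
    raw[[cc]] <- conv
  }
  tat0 <- if ("tat0" %in% names(raw)) raw$tat0 else rep(0, nrow(raw))
  R <- if ("R" %in% names(raw)) raw$R else rep(0, nrow(raw))
  key <- paste(tat0, R, sep = "/")
  build <- function(idx) {
    d <- raw[idx, ]
    if (any(duplicated(d$time_h)))
      stop("duplicated time point within a condition", call. = FALSE)
    if (is.unsorted(d$time_h, strictly = TRUE))
      stop("times must be sorted increasing within a condition",
           call. = FALSE)
    dsb_observations(d$time_h, d$chi1, d$chi2, chi1_bar = d[["chi1_bar"]],
                     tat0 = tat0[idx][1], R = R[idx][1])
  }
  if (length(unique(key)) == 1L) return(build(seq_len(nrow(raw))))
  out <- lapply(split(seq_len(nrow(raw)), key), build)
  out[order(vapply(out, function(o) attr(o, "tat0"), numeric(1)))]
}

#' @rdname read_observations
#' @param obs a `dsb_obs` (or plain data frame with the schema above).
#' @param manifest write a YAML manifest beside the CSV recording the
#'   generating truth and seed when the observations carry them.
#' @export
write_observations <- function(obs, path, manifest = FALSE) {
  df <- as.data.frame(obs)
  tat0 <- attr(obs, "tat0")
  if (!is.null(tat0) && tat0 != 0 && !"tat0" %in% names(df)) df$tat0 <- tat0
  Rsa <- attr(obs, "R")
  if (!is.null(Rsa) && Rsa != 0 && !"R" %in% names(df)) df$R <- Rsa
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), NA, format(v, digits = 15, trim = TRUE,
                                scientific = FALSE))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  if (isTRUE(manifest)) {
    man <- list(n_dsb0 = attr(obs, "n_dsb0"), tat0 = tat0, R = Rsa,
                cv = attr(obs, "cv"), seed = attr(obs, "seed"),
                generator = attr(obs, "generator"))
    truth <- attr(obs, "truth")
    if (!is.null(truth))
      man$truth <- as.list(setNames(as.numeric(truth), paste0("k", 1:6)))
    ext <- attr(obs, "ext")
    if (!is.null(ext))
      man$ext <- as.list(setNames(as.numeric(ext), names(unclass(ext))))
    yaml::write_yaml(man[!vapply(man, is.null, logical(1))],
                     paste0(tools::file_path_sans_ext(path), "_manifest.yaml"))
  }
  invisible(path)
}
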