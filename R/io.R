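# File formats: PMF profiles and dihedral series as whitespace-delimited
# text with '#' metadata headers; cycle contributions as CSV; results as
# JSON validated against the in-repo schema.

#' Write / read a PMF profile as two-column text
#'
#' Header lines start with `#`; `# key=value` lines carry metadata (`cv`,
#' `bin_width`, `temperature`, `estimator`, ...), other `#` lines are
#' tolerated and preserved, so Colvars-style `.pmf` files parse.  The data
#' block is two whitespace-separated columns (bin centre, free energy), with
#' optional third/fourth columns (count, gradient) on writing.
#'
#' @param pmf a [pmf_profile()]
#' @param path file path
#' @return `read_pmf()`: a [pmf_profile()]; round-trip write/read preserves
#'   values to full double precision
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(cv = pmf$cv_kind, bin_width = pmf$bin_width,
            temperature = pmf$temperature, estimator = pmf$estimator)
  extra <- pmf$metadata[setdiff(names(pmf$metadata), c(names(meta), "gaps"))]
  for (nm in names(meta))
    writeLines(sprintf("# %s=%s", nm, format(meta[[nm]], digits = 17)), con)
  for (nm in names(extra))
    writeLines(sprintf("# %s=%s", nm, format(extra[[nm]], digits = 17)), con)
  cols <- cbind(pmf$centers, pmf$value)
  if (!is.null(pmf$count)) cols <- cbind(cols, pmf$count)
  if (!is.null(pmf$gradient)) cols <- cbind(cols, pmf$gradient)
  writeLines(apply(cols, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = " ")), con)
  invisible(path)
}

#' @rdname write_pmf
#' @param temperature fallback temperature (K) when the file metadata has
#'   none (composition needs beta; an error is raised if both are absent)
#' @export
read_pmf <- function(path, temperature = NULL) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- grep("^\\s*#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in '", path, "'")
  meta <- list()
  for (h in hdr) {
    h2 <- sub("^\\s*#\\s*", "", h)
    if (grepl("=", h2, fixed = TRUE)) {
      kv <- strsplit(h2, "=", fixed = TRUE)[[1]]
      meta[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  fields <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
  ncol <- unique(vapply(fields, length, integer(1)))
  if (length(ncol) != 1 || ncol[1] < 2)
    stop("expected at least two whitespace-separated numeric columns")
  M <- do.call(rbind, fields)
  if (any(diff(M[, 1]) <= 0))
    stop("bin centres must be strictly increasing (shuffled or corrupt file)")
  tem <- if (!is.null(meta$temperature)) as.numeric(meta$temperature)
         else temperature
  if (is.null(tem) || !is.finite(tem))
    stop("no temperature in file metadata; pass `temperature =` explicitly ",
         "(free-energy composition needs beta)")
  pmf_profile(M[, 1], M[, 2],
              count = if (ncol >= 3) M[, 3],
              gradient = if (ncol >= 4) M[, 4],
              cv_kind = if (!is.null(meta$cv)) meta$cv else "unknown",
              temperature = tem,
              estimator = if (!is.null(meta$estimator)) meta$estimator
                          else "file",
              metadata = meta, anchor = "none")
}

#' Write / read a dihedral time series
#'
#' Two whitespace-separated columns (phi1, phi2) in degrees with a `#`
#' header.
#'
#' @param series a [dihedral_series()]
#' @param path file path
#' @export
write_dihedral_series <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# phi1_deg phi2_deg", con)
  st <- attr(series, "stride_ps")
  if (!is.null(st) && is.finite(st))
    writeLines(sprintf("# stride_ps=%g", st), con)
  writeLines(sprintf("%.10g %.10g", series$phi1, series$phi2), con)
  invisible(path)
}

#' @rdname write_dihedral_series
#' @export
read_dihedral_series <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  M <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  if (ncol(M) < 2) stop("expected two columns (phi1, phi2)")
  st <- NA_real_
  h <- grep("stride_ps=", hdr, value = TRUE)
  if (length(h)) st <- as.numeric(sub(".*stride_ps=", "", h[1]))
  dihedral_series(M[, 1], M[, 2], stride_ps = st)
}

#' Read cycle contributions from CSV
#'
#' Columns: `name`, `dg_kcal_mol`, optional `error_kcal_mol`, `time_ns` --
#' one row per term of the binding cycle.
#'
#' @param path CSV path
#' @return list of [cycle_contribution()]s
#' @export
read_contributions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "dg_kcal_mol")
  if (!all(need %in% names(df)))
    stop("contributions file needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    cycle_contribution(df$name[i], df$dg_kcal_mol[i],
                       error = if ("error_kcal_mol" %in% names(df))
                         df$error_kcal_mol[i] else NA_real_,
                       time_ns = if ("time_ns" %in% names(df))
                         df$time_ns[i] else NA_real_))
}

#' Serialize a cycle result as JSON
#'
#' The JSON object follows the schema shipped at
#' `system.file("schema", "cycle_result.json", package = "geomroute")`.
#'
#' @param result a `cycle_result` from [compose_cycle()]
#' @param path output path (NULL returns the JSON string)
#' @param seed optional seed to record for reproducibility
#' @export
write_cycle_json <- function(result, path = NULL, seed = NULL) {
  stopifnot(inherits(result, "cycle_result"))
  obj <- list(
    schema_version = "1.0",
    dg_bind_kcal_mol = result$dg_bind,
    error_kcal_mol = if (is.na(result$error)) NULL else result$error,
    keq_A3 = result$keq,
    v0_A3 = result$v0,
    temperature_K = result$temperature,
    time_ns = if (is.na(result$time_ns)) NULL else result$time_ns,
    seed = seed,
    contributions = lapply(result$contributions, function(ct)
      list(name = ct$name, dg_kcal_mol = ct$dg,
           error_kcal_mol = if (is.na(ct$error)) NULL else ct$error,
           time_ns = if (is.na(ct$time_ns)) NULL else ct$time_ns)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  validate_cycle_json(jsonlite::fromJSON(js, simplifyVector = FALSE))
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

# minimal structural validation against the shipped schema
validate_cycle_json <- function(obj) {
  schema_path <- system.file("schema", "cycle_result.json",
                             package = "geomroute")
  req <- c("schema_version", "dg_bind_kcal_mol", "keq_A3", "v0_A3",
           "temperature_K", "contributions")
  if (nzchar(schema_path)) {
    sch <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
    req <- unlist(sch$required)
  }
  miss <- setdiff(req, names(obj))
  if (length(miss))
    stop("cycle result JSON missing required field(s): ",
         paste(miss, collapse = ", "))
  if (!is.numeric(obj$dg_bind_kcal_mol))
    stop("dg_bind_kcal_mol must be a number")
  if (length(obj$contributions) != 9)
    stop("cycle result must carry nine contributions")
  invisible(TRUE)
}
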