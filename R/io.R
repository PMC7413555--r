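#' Write a force curve to columnar text
#'
#' Tab-separated columns `time_s`, `indentation_m`, `force_N`, `phase`
#' (SI units) or `time_s`, `indentation_nm`, `force_nN`, `phase` (AFM
#' convention), values printed with `%.12e` so a write-read round trip is
#' exact to text precision.  Metadata (model, probe, ramp, contact time) go
#' into `#`-prefixed header lines and, optionally, a JSON sidecar.
#'
#' @param curve a `force_curve`.
#' @param path output file.
#' @param units `"si"` (m, N) or `"afm"` (nm, nN).
#' @param normalized also write `indentation_norm`, `force_norm` columns?
#' @param sidecar write `<path>.json` with the metadata?
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path, units = c("si", "afm"),
                              normalized = FALSE, sidecar = FALSE) {
  stopifnot(inherits(curve, "force_curve"))
  units <- match.arg(units)
  d <- as.data.frame(curve, normalized = normalized)
  scale <- if (units == "afm") 1e9 else 1
  meta <- curve_meta(curve)
  cols <- if (units == "afm") c("time_s", "indentation_nm", "force_nN")
          else c("time_s", "indentation_m", "force_N")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# viscoind force curve"),
               sprintf("# units: time=s depth=%s force=%s",
                       if (units == "afm") "nm" else "m",
                       if (units == "afm") "nN" else "N"),
               sprintf("# model: %s", meta$model$name),
               sprintf("# t_m_s: %.12e", curve$t_m),
               sprintf("# t_detach_s: %.12e", curve$t_detach)), con)
  out <- data.frame(fmt12(d$time_s), fmt12(d$indentation_m * scale),
                    fmt12(d$force_N * scale), d$phase)
  names(out) <- c(cols, "phase")
  if (normalized) {
    out$indentation_norm <- fmt12(d$indentation_norm)
    out$force_norm <- fmt12(d$force_norm)
  }
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

fmt12 <- function(x) sprintf("%.12e", x)

curve_meta <- function(curve) {
  list(model = list(name = curve$model$name, params = curve$model$params,
                    delta_coeff = curve$model$delta_coeff),
       probe = list(shape = curve$probe$shape,
                    dimension = as.list(curve$probe$dimension),
                    nu = curve$probe$nu,
                    nu_correction = curve$probe$nu_correction),
       ramp = list(kind = curve$history$kind,
                   delta_max = curve$history$delta_max,
                   t_m = curve$history$t_m),
       t_m = curve$t_m, t_detach = curve$t_detach, t_ind = curve$t_ind,
       n_steps = curve$n_steps, method = curve$method)
}

#' Read a force curve from columnar text
#'
#' Accepts files written by [write_force_curve()] and, more generally, any
#' whitespace/tab-separated file whose header names a time column and
#' depth/force columns with unit suffixes (`_m`/`_nm`, `_N`/`_nN`).  A
#' missing `phase` column is reconstructed by splitting at the depth
#' maximum.
#'
#' @param path input file.
#' @return a data frame with columns `time_s`, `indentation_m`, `force_N`,
#'   `phase` (SI units).
#' @export
read_force_curve <- function(path) {
  d <- read.table(path, header = TRUE, sep = "", comment.char = "#",
                  stringsAsFactors = FALSE)
  nm <- names(d)
  tcol <- grep("^time", nm, value = TRUE)[1]
  dcol <- grep("^(indentation|depth|delta)", nm, value = TRUE)[1]
  fcol <- grep("^force", nm, value = TRUE)[1]
  if (anyNA(c(tcol, dcol, fcol)))
    stop("malformed curve file: need time, indentation and force columns")
  dscale <- if (grepl("_nm$", dcol)) 1e-9 else 1
  fscale <- if (grepl("_nN$", fcol)) 1e-9 else 1
  out <- data.frame(time_s = d[[tcol]],
                    indentation_m = d[[dcol]] * dscale,
                    force_N = d[[fcol]] * fscale,
                    stringsAsFactors = FALSE)
  if ("phase" %in% nm) {
    out$phase <- d$phase
  } else {
    imax <- which.max(out$indentation_m)
    out$phase <- rep(c("approach", "retract"),
                     c(imax, nrow(out) - imax))
  }
  out
}

#' Write a metrics sweep table
#'
#' TSV with columns `t_ind_s`, `t_norm`, `t_contact_s`, `YM_Pa`, `YM_norm`,
#' `NHA`, `exponent`, plus an optional JSON metadata sidecar.
#'
#' @param sweep an [sweep_indentation_time()] result.
#' @param path output file.
#' @param sidecar write `<path>.json` with model/probe/ramp metadata?
#' @return `path`, invisibly.
#' @export
write_metrics <- function(sweep, path, sidecar = FALSE) {
  stopifnot(inherits(sweep, "indentation_sweep"))
  d <- as.data.frame(sweep)
  d[] <- lapply(d, fmt12)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    m <- attr(sweep, "model"); p <- attr(sweep, "probe")
    jsonlite::write_json(
      list(model = list(name = m$name, params = m$params),
           probe = list(shape = p$shape, dimension = as.list(p$dimension)),
           ramp = attr(sweep, "kind"), normalize = attr(sweep, "normalize")),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Configuration schema: `model: {name, params: {...}}`,
#' `probe: {shape, radius | half_angle, nu, nu_correction}`,
#' `ramp: {kind, delta_max, t_m}` (`delta_max` in m, or a string with an
#' `nm` suffix), optional `solver: {n_steps, method}`,
#' `sweep: {t_ind: [..] | {from, to, length}}`, `output: {path, units}`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a named list.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("config must be a .yaml/.yml or .json file")
}
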