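format_error <- function(msg, ...) {
  cond <- structure(class = c("ssb_format_error", "error", "condition"),
                    list(message = sprintf(msg, ...), call = sys.call(-1)))
  stop(cond)
}

#' Write a trace to CSV with a JSON sidecar
#'
#' The CSV holds the canonical columns `time_s,compaction_nm_per_nt`
#' (locale-independent decimal points, full precision); a `<path>.json`
#' sidecar records the protocol, generating parameters, noise model and
#' seed so the trace is exactly regenerable.
#'
#' @param trace an `ssb_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "ssb_trace"))
  ## %.17g round-trips doubles exactly; C locale decimal points
  lines <- c("time_s,compaction_nm_per_nt",
             sprintf("%.17g,%.17g", trace$time_s,
                     trace$compaction_nm_per_nt))
  writeLines(lines, path)
  prot <- attr(trace, "protocol")
  params <- attr(trace, "params")
  noise <- attr(trace, "noise")
  meta <- list(
    package = "ssbkinetics",
    version = as.character(utils::packageVersion("ssbkinetics")),
    ideal = isTRUE(attr(trace, "ideal")),
    seed = attr(trace, "seed"),
    sampling_rate_hz = if (!is.null(prot)) attr(prot, "sampling_rate"),
    protocol = if (!is.null(prot))
      list(label = attr(prot, "label"),
           segments = as.data.frame(unclass(prot)[c("duration_s", "conc_nM",
                                                    "force_pN")])),
    parameters = if (!is.null(params)) params_to_json_list(params),
    noise = if (!is.null(noise))
      list(sigma_nm_per_nt = noise$sigma,
           drift_nm_per_nt_per_100s = noise$drift_rate,
           seed = noise$seed))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' Round-trips values at full precision. A missing canonical column raises
#' a format error naming the column.
#'
#' @param path CSV path.
#' @return An `ssb_trace` (without theta columns; protocol metadata is
#'   attached from the sidecar when present).
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("time_s", "compaction_nm_per_nt")) {
    if (!col %in% names(df))
      format_error("trace file %s is missing required column '%s'",
                   path, col)
  }
  if (!is.numeric(df$time_s) || !is.numeric(df$compaction_nm_per_nt))
    format_error("trace file %s has non-numeric values", path)
  tr <- structure(
    data.frame(time_s = df$time_s,
               compaction_nm_per_nt = df$compaction_nm_per_nt),
    ideal = NA, class = c("ssb_trace", "data.frame"))
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    attr(tr, "ideal") <- isTRUE(meta$ideal)
    attr(tr, "seed") <- meta$seed
    if (!is.null(meta$protocol)) {
      seg <- do.call(rbind, lapply(meta$protocol$segments, as.data.frame))
      if (!is.null(seg)) {
        attr(tr, "protocol") <- protocol(
          seg$duration_s, seg$conc_nM, seg$force_pN,
          sampling_rate = meta$sampling_rate_hz %||% 10,
          label = meta$protocol$label %||% "protocol")
      }
    }
  }
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

params_to_json_list <- function(params) {
  list(
    label = params$label,
    force_pN = params$force,
    k_b_per_nM_s = params$k_b,
    rates_s_inv = list(k_off = params$k_off, k_w = params$k_w,
                       k_unw = params$k_unw,
                       k_off_stim = params$k_off_stim,
                       k_unw_stim = params$k_unw_stim),
    footprints_nt = list(bound = params$n_b, wrapped = params$n_w),
    compaction_nm_per_nt = list(bound = params$x_b, wrapped = params$x_w),
    wrapping = params$wrapping,
    availability = params$availability)
}

#' Serialize a parameter set to JSON
#'
#' Unit-bearing field names (`k_b_per_nM_s`, `rates_s_inv`,
#' `footprints_nt`, `compaction_nm_per_nt`, `force_pN`) make the files
#' self-describing; [read_parameter_set()] reads them back.
#'
#' @param params an `ssb_params` object.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  jsonlite::write_json(params_to_json_list(params), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  j <- jsonlite::read_json(path)
  need <- c("k_b_per_nM_s", "rates_s_inv", "footprints_nt",
            "compaction_nm_per_nt")
  for (f in need) if (is.null(j[[f]]))
    format_error("parameter file %s is missing field '%s'", path, f)
  parameter_set(
    k_b = j$k_b_per_nM_s,
    k_off = j$rates_s_inv$k_off, k_w = j$rates_s_inv$k_w,
    k_unw = j$rates_s_inv$k_unw %||% 0,
    k_off_stim = j$rates_s_inv$k_off_stim %||% 0,
    k_unw_stim = j$rates_s_inv$k_unw_stim %||% 0,
    n_b = j$footprints_nt$bound, n_w = j$footprints_nt$wrapped,
    x_b = j$compaction_nm_per_nt$bound, x_w = j$compaction_nm_per_nt$wrapped,
    force = j$force_pN %||% 12,
    wrapping = j$wrapping %||% TRUE,
    availability = j$availability %||% "rationed",
    label = j$label %||% basename(path))
}

#' Serialize a protocol to JSON
#'
#' @param prot an `ssb_protocol`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_protocol <- function(prot, path) {
  jsonlite::write_json(
    list(label = attr(prot, "label"),
         sampling_rate_hz = attr(prot, "sampling_rate"),
         mixing_s = attr(prot, "mixing_s"),
         segments = data.frame(duration_s = prot$duration_s,
                               conc_nM = prot$conc_nM,
                               force_pN = prot$force_pN)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  if (!file.exists(path)) format_error("file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$segments))
    format_error("protocol file %s is missing field 'segments'", path)
  protocol(j$segments$duration_s, j$segments$conc_nM, j$segments$force_pN,
           sampling_rate = j$sampling_rate_hz %||% 10,
           mixing_s = j$mixing_s %||% 0,
           label = j$label %||% basename(path))
}
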