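#' Read a flat key = value configuration file
#'
#' The configuration format is plain text, one `key = value` pair per
#' line; `#` starts a comment (units are conventionally documented in
#' comments).  Keys are model parameter names ([hco_parameters()]),
#' kinetics constants ([kinetics_constants()]) prefixed with `kinetics.`,
#' or protocol settings prefixed with `protocol.` (transient, record,
#' sample_dt).  Unknown keys are rejected.
#'
#' @param path file path.
#' @return List with `params` (an `hco_parameters`), and `protocol`
#'   (named list of any protocol overrides present).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "), call. = FALSE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  if (any(is.na(vals))) {
    stop("non-numeric value for key(s): ",
         paste(keys[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  par_names <- setdiff(names(formals(hco_parameters)), "kinetics")
  kin_names <- names(formals(kinetics_constants))
  proto_names <- c("transient", "record", "sample_dt")
  par_args <- list()
  kin_args <- list()
  proto <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (startsWith(k, "kinetics.")) {
      kk <- sub("^kinetics\\.", "", k)
      if (!kk %in% kin_names) stop("unknown kinetics key: ", k,
                                   call. = FALSE)
      kin_args[[kk]] <- vals[i]
    } else if (startsWith(k, "protocol.")) {
      kk <- sub("^protocol\\.", "", k)
      if (!kk %in% proto_names) stop("unknown protocol key: ", k,
                                     call. = FALSE)
      proto[[kk]] <- vals[i]
    } else if (k %in% par_names) {
      par_args[[k]] <- vals[i]
    } else {
      stop("unknown config key: ", k, call. = FALSE)
    }
  }
  par_args$kinetics <- do.call(kinetics_constants, kin_args)
  list(params = do.call(hco_parameters, par_args), protocol = proto)
}

#' Write a configuration file for a parameter set
#'
#' Writes every model parameter and kinetics constant as `key = value`
#' lines; [load_config()] on the result reproduces the parameter set
#' exactly (round-trip identity).
#'
#' @param params an [hco_parameters()] object.
#' @param path output file path.
#' @param protocol optional named list (transient, record, sample_dt).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, protocol = NULL) {
  par_names <- setdiff(names(formals(hco_parameters)), "kinetics")
  lines <- c("# model parameters (units: mV, s, nS, pA, nF, mM)",
             sprintf("%s = %.17g", par_names,
                     vapply(par_names, function(k) params[[k]], 0)),
             "# kinetics constants",
             sprintf("kinetics.%s = %.17g", names(params$kinetics),
                     unlist(params$kinetics)))
  if (length(protocol)) {
    lines <- c(lines, "# protocol",
               sprintf("protocol.%s = %.17g", names(protocol),
                       unlist(protocol)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated trace to CSV
#'
#' Column headers are `time_s` followed by the trace's channel names
#' (`Vm.1` becomes `vm1_mV`, `Nai.2` becomes `nai2_mM`, `mh.1` becomes
#' `mh1`, and analogously for single-cell traces); metadata (parameters
#' and protocol) is stored in `#`-prefixed comment header lines.
#'
#' @param trace an `hco_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  nm <- colnames(trace$channels)
  unit_of <- function(x) {
    if (startsWith(x, "Vm")) "mV" else if (startsWith(x, "Nai")) "mM"
    else ""
  }
  col <- vapply(nm, function(x) {
    parts <- strsplit(x, ".", fixed = TRUE)[[1]]
    base <- tolower(parts[1])
    idx <- if (length(parts) > 1) parts[2] else ""
    u <- unit_of(x)
    paste0(base, idx, if (nzchar(u)) paste0("_", u) else "")
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# hcorhythm trace: %d cell(s), sample_dt %.6g s, transient %.6g s",
            trace$ncell, trace$sample_dt, trace$transient),
    sprintf("# gh %.6g nS, IPumpMax %.6g pA, gSyn %.6g nS, M %.6g 1/s, tau_h_scale %.6g",
            trace$params$gh, trace$params$IPumpMax, trace$params$gSyn,
            trace$params$M, trace$params$tau_h_scale)), con)
  df <- data.frame(time_s = trace$time, trace$channels,
                   check.names = FALSE)
  colnames(df) <- c("time_s", col)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace()]
#'
#' @param path CSV path.
#' @return A data.frame with `time_s` and the channel columns (comment
#'   header lines skipped).
#' @export
read_trace <- function(path) {
  utils::read.csv(path, comment.char = "#", check.names = FALSE)
}

#' Write rhythm metrics to CSV
#'
#' One row per burst and per episode plus a summary block, all in long
#' format (`section`, `index`, `field`, `value`).
#'
#' @param metrics a `rhythm_metrics`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  rows <- data.frame(section = character(0), index = integer(0),
                     field = character(0), value = numeric(0))
  b <- metrics$bursts
  for (i in seq_len(nrow(b))) {
    rows <- rbind(rows, data.frame(
      section = "burst", index = i,
      field = c("onset", "offset", "n_spikes"),
      value = c(b$onset[i], b$offset[i], b$n_spikes[i])))
  }
  e <- metrics$episodes
  for (i in seq_len(nrow(e))) {
    rows <- rbind(rows, data.frame(
      section = "episode", index = i,
      field = c("onset", "offset", "n_bursts"),
      value = c(e$onset[i], e$offset[i], e$n_bursts[i])))
  }
  s <- metrics$summary
  for (i in seq_len(nrow(s))) {
    rows <- rbind(rows, data.frame(
      section = "summary", index = i,
      field = paste0(s$metric[i], c("_mean", "_sd", "_cv", "_n")),
      value = c(s$mean[i], s$sd[i], s$cv[i], s$n[i])))
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
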