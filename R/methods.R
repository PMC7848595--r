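# Methods and I/O for beat traces.

#' @export
print.beat_trace <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<beat_trace> %s%s, %d beats at CL %g ms, %d samples (dt %g ms)\n",
              toupper(meta$variant %||% "?"),
              if (isTRUE(meta$coupled)) "+Land" else "",
              length(attr(x, "stim_times")), attr(x, "cl"), nrow(x),
              attr(x, "dt_out")))
  cat(sprintf("  V in [%.1f, %.1f] mV, CaT peak %.3g mM, Ta peak %.2f kPa\n",
              min(x$v), max(x$v), max(x$cai), max(x$ta)))
  invisible(x)
}

#' @export
summary.beat_trace <- function(object, ...) {
  nb <- length(attr(object, "stim_times"))
  print(object)
  cat("last-beat biomarkers:\n")
  print(biomarkers(object, nb))
  invisible(object)
}

#' @export
plot.beat_trace <- function(x, beats = NULL, ...) {
  st <- attr(x, "stim_times")
  if (!is.null(beats)) {
    keep <- rep(FALSE, nrow(x))
    for (b in beats) {
      w <- .beat_window(x, b)
      keep <- keep | w$idx
    }
    x <- x[keep, ]
  }
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$v, type = "l", xlab = "", ylab = "V (mV)", ...)
  graphics::plot(x$t, 1000 * x$cai, type = "l", xlab = "",
                 ylab = expression("[Ca]"[i] * " (uM)"), ...)
  graphics::plot(x$t, x$ta, type = "l", xlab = "t (ms)",
                 ylab = "Ta (kPa)", ...)
  invisible(x)
}

#' Write / read a beat trace as CSV
#'
#' CSV with `#`-prefixed header metadata lines (variant, celltype, coupling,
#' cycle length, stimulus times) followed by the columns of the trace.
#'
#' @param trace a `beat_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  meta <- attr(trace, "meta")
  hdr <- c(
    sprintf("# emcell beat_trace v%d", STATE_VERSION),
    sprintf("# variant=%s celltype=%s coupled=%s", meta$variant,
            meta$celltype, isTRUE(meta$coupled)),
    sprintf("# cl=%g dt_out=%g", attr(trace, "cl"), attr(trace, "dt_out")),
    sprintf("# stim_times=%s", paste(attr(trace, "stim_times"),
                                     collapse = ",")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "#")]
  gv <- function(key, line) {
    m <- regmatches(line, regexec(paste0(key, "=([^ ]+)"), line))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  meta_line <- hdr[grepl("variant=", hdr)]
  cl_line <- hdr[grepl("cl=", hdr)]
  st_line <- hdr[grepl("stim_times=", hdr)]
  df <- utils::read.csv(path, comment.char = "#")
  structure(df, class = c("beat_trace", "data.frame"),
            stim_times = as.numeric(strsplit(gv("stim_times", st_line),
                                             ",")[[1]]),
            cl = as.numeric(gv("cl", cl_line)),
            dt_out = as.numeric(gv("dt_out", cl_line)),
            meta = list(variant = gv("variant", meta_line),
                        celltype = gv("celltype", meta_line),
                        coupled = gv("coupled", meta_line) == "TRUE",
                        cl = as.numeric(gv("cl", cl_line))))
}

#' @export
plot.dose_response <- function(x, ...) {
  d <- x$data
  graphics::plot(d$conc, d$reduction, log = "x", pch = 19,
                 xlab = "concentration (uM)",
                 ylab = "peak tension reduction (%)",
                 ylim = c(0, 100), ...)
  cc <- 10^seq(log10(min(d$conc)), log10(max(d$conc)), length.out = 200)
  graphics::lines(cc, 100 * block_fraction(cc, x$ic50, x$hill))
  graphics::abline(h = 50, lty = 3)
  invisible(x)
}
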