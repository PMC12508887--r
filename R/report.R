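#' Render a markdown summary report for an analysis bundle
#'
#' Writes a single self-contained markdown report: run provenance, the
#' cluster summary with per-cluster mean-spectrum difference peaks, and
#' one section per metabolite window with its compartment mean +/- SD
#' table.  Regeneration from the same bundle is byte-stable (no
#' timestamps are embedded).
#'
#' @param bundle an \code{mqaBundle} from \code{\link{runMQA}}.
#' @param path output markdown file.
#' @return invisibly, the path.
#' @export
reportBundle <- function(bundle, path) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, ...)
  add("# Semi-quantitative Raman analysis report", "")
  pv <- bundle$provenance
  add("## Run", "",
      sprintf("- seed: %s", pv$seed),
      sprintf("- clusters (k): %s", pv$k),
      sprintf("- internal standard: %s cm^-1", pv$internalStandard),
      sprintf("- metabolite windows: %s",
              paste(pv$windows, collapse = ", ")),
      "")
  if (is(bundle$clusters, "ClusterResult")) {
    cl <- bundle$clusters
    add("## Compartments", "",
        sprintf("- %d clusters over %d x %d pixels", cl@k, cl@height,
                cl@width))
    pk <- tryCatch(differencePeaks(cl), error = function(e) NULL)
    if (!is.null(pk)) {
      ann <- annotateClusters(pk)
      for (i in seq_len(nrow(ann)))
        add(sprintf("- %s: class %s (bands: %s)", ann$cluster[i],
                    ann$class[i],
                    if (nzchar(ann$bands[i])) ann$bands[i] else "none"))
    }
    add("")
  }
  st <- bundle$stats
  if (is.null(st) || !nrow(st)) {
    add("## Statistics", "", "no valid compartments", "")
  } else {
    for (met in unique(st$metabolite)) {
      add(sprintf("## %s", met), "",
          "| group | compartment | n | mean dA | SD |",
          "|---|---|---|---|---|")
      sub <- st[st$metabolite == met, , drop = FALSE]
      for (i in seq_len(nrow(sub)))
        add(sprintf("| %s | %s | %d | %.4g | %.4g |",
                    sub$group[i], sub$label[i], sub$n[i], sub$mean[i],
                    sub$sd[i]))
      add("")
    }
  }
  writeLines(ln, path)
  invisible(path)
}
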