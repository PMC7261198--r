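#!/usr/bin/env Rscript
# Calibration of the helix-coil default weights.
#
# Scans the three-class propagation weights (w for non-Pro/Gly, w_pro,
# w_gly) and the nucleation weight v, and reports the exact (transfer-
# matrix) per-window helical propensity of each bundled subtype basic
# subregion with charges off. The shipped defaults (w = 2.0, w_pro = 0.02,
# w_gly = 0.3, v = 0.05) were chosen from this scan as a point where the
# neutralized propensity ordering H1.0 > H1.2 > H1.1 holds with a clear
# margin while overall helicity stays moderate; the scan shows the ordering
# is stable over a broad neighbourhood, not a knife-edge.
#
# usage: Rscript scripts/calibrate_model.R

suppressPackageStartupMessages(library(ntdfold))

subs <- lapply(ntd_fixture_sequences(), extract_basic_subregion)

propensities <- function(w, w_pro, w_gly, v) {
  vapply(subs, function(s) {
    transfer_matrix_salpha(
      model_params(s,
        w = w, w_pro = w_pro, w_gly = w_gly, v = v,
        neutralized = TRUE
      ),
      normalized = TRUE
    )
  }, numeric(1))
}

grid <- expand.grid(
  w = c(1.3, 1.5, 1.7, 2.0, 2.4),
  w_pro = c(0.02, 0.1),
  w_gly = c(0.2, 0.3, 0.5),
  v = c(0.02, 0.05, 0.1)
)

rows <- lapply(seq_len(nrow(grid)), function(i) {
  g <- grid[i, ]
  p <- propensities(g$w, g$w_pro, g$w_gly, g$v)
  cbind(g,
    h10 = p[["H1.0"]], h11 = p[["H1.1"]], h12 = p[["H1.2"]],
    ordered = p[["H1.0"]] > p[["H1.2"]] && p[["H1.2"]] > p[["H1.1"]],
    margin = min(p[["H1.0"]] - p[["H1.2"]], p[["H1.2"]] - p[["H1.1"]])
  )
})
tab <- do.call(rbind, rows)
tab[, c("h10", "h11", "h12", "margin")] <-
  round(tab[, c("h10", "h11", "h12", "margin")], 4)
print(tab, row.names = FALSE)

cat(sprintf(
  "\n%d of %d scanned parameter sets reproduce the ordering\n",
  sum(tab$ordered), nrow(tab)
))
def <- propensities(2.0, 0.02, 0.3, 0.05)
cat("shipped defaults:",
  sprintf("%s = %.4f", names(def), def), "\n")
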