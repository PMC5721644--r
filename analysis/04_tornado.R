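#!/usr/bin/env Rscript
# One-way deterministic sensitivity analysis: every utility value, unit cost
# and visit count varied by ±50%, ranked by its leverage on the net monetary
# benefit of early PRP at £20,000/QALY.

suppressPackageStartupMessages(library(prpcea))

pack <- load_pack("results/inputs/base_case_pack.yaml")
tor <- report_tornado(pack, "results/tornado", wtp = 20000)

cat(sprintf("Base-case NMB at £20,000/QALY: £%.0f\n\n", attr(tor, "base_nmb")))
cat("Widest tornado bars:\n")
print(utils::head(tor, 8), row.names = FALSE, digits = 5)

svl <- tor[tor$parameter == "utilities.svl", ]
cat(sprintf("\nSevere-visual-loss utility: NMB £%.0f at x1.5 (capped at 1.00), £%.0f at x0.5
— the better blindness is tolerated, the less early treatment is worth.\n",
            svl$nmb_high, svl$nmb_low))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  ggplot2::ggsave("results/tornado/tornado.png", plot_tornado(tor),
                  width = 7, height = 4.5, dpi = 150)
  cat("\nFigure written to results/tornado/tornado.png.\n")
}
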