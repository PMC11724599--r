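#!/usr/bin/env Rscript
# Species comparisons with tie-corrected Kruskal-Wallis rank-sum tests
# (Dunn/Bonferroni post hoc where the omnibus test is significant and more
# than two groups are compared): arrival and departure timing, residence
# duration, RI (return years), station counts and land-clipped MCP areas.

suppressPackageStartupMessages(library(mullettrack))

res <- utils::read.csv("results/residence.csv")
res$arrival <- mullettrack:::parse_timestamp(res$arrival)
res$departure <- mullettrack:::parse_timestamp(res$departure)
mcp_tab <- utils::read.csv("results/mcp.csv")

ret <- res[res$included & res$is_return_year, ]
ret$arrival_doy <- doy(ret$arrival)
ret$departure_doy <- doy(ret$departure)

rows <- list()
for (metric in c("arrival_doy", "departure_doy", "duration_days", "RI")) {
  rows[[metric]] <- compare_species(ret, metric)
}
space <- res[res$included, ]
rows$n_stations <- compare_species(space, "n_stations")
rows$mcp <- compare_species(mcp_tab[!mcp_tab$degenerate, ], "clipped_area_km2")

tab <- comparison_table(rows)
write_dataset(tab, "results/stats_report.csv")
tab$H <- round(tab$H, 3)
tab$p_value <- signif(tab$p_value, 3)
print(as.data.frame(tab[, c("metric", "H", "df", "p_value", "significant")]),
      row.names = FALSE)

for (metric in c("RI", "arrival_doy")) {
  cm <- rows[[metric]]
  cat(sprintf("\n%s: chi-squared = %.3f, df = %d, p = %.4g\n",
              metric, cm$kw$H, cm$kw$df, cm$kw$p_value))
}
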