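#!/usr/bin/env Rscript
# Recovery analysis: per-zone recovery degree RNTL against the
# lunar-matched baseline for the February (19-29 Feb) and March (1-31 Mar)
# recovery windows, verified against the mobility-index recovery ratio m,
# plus the March-minus-February D-value.

library(nightshift)
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(pipeline_config(seed = 1))
rec <- res$recovery

write.csv(rec$feb, "results/recovery_feb.csv", row.names = FALSE)
write.csv(rec$mar, "results/recovery_mar.csv", row.names = FALSE)
write.csv(rec$d_value, "results/recovery_d_value.csv", row.names = FALSE)
write.csv(as.data.frame(rec$crosstab$table),
          "results/recovery_crosstab.csv", row.names = FALSE)

cat(sprintf("February recovery degrees: %s.\n",
            paste(sprintf("%.2f", rec$feb$rntl), collapse = ", ")))
cat(sprintf("March recovery degrees:    %s.\n",
            paste(sprintf("%.2f", rec$mar$rntl), collapse = ", ")))
cat(sprintf("Zones above 60%% by light: %d; of those, above 60%% by mobility: %d (agreement %.2f).\n",
            rec$crosstab$agreement$n_ntl_above,
            rec$crosstab$agreement$n_both_above,
            rec$crosstab$agreement$fraction))
cat(sprintf("D-values (Mar - Feb): %s — %s.\n",
            paste(sprintf("%+.2f", rec$d_value$d_value), collapse = ", "),
            if (all(rec$d_value$d_value >= 0)) "steady recovery everywhere"
            else "fluctuating recovery in some zones"))
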