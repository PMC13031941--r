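#!/usr/bin/env Rscript
# The worst-case masking correction: from the survey's shot logs (66,898
# and 84,417 shots over 432 and 384 h) and the published per-instrument
# quiet/shooting means, rebuild the full corrected detection table and its
# audit trail of exact intermediates.

library(finpulse)

dir.create("results", showWarnings = FALSE)

tb <- build_table1()
print(tb)

utils::write.csv(tb$table, "results/masking_table.csv", row.names = FALSE)
jsonlite::write_json(
  c(tb$audit,
    list(mean_drop_observed = tb$mean_drop_observed,
         mean_drop_worst_case = tb$mean_drop_worst_case,
         factor_applied = tb$factor, notes = tb$notes)),
  "results/masking_audit.json", auto_unbox = TRUE, digits = NA)

message(sprintf(
  "observed drops average %.1f%%; even under worst-case masking the drops remain %.1f-%.1f%%",
  tb$mean_drop_observed, min(tb$table$pct_drop_worst_case),
  max(tb$table$pct_drop_worst_case)))
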