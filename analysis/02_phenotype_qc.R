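#!/usr/bin/env Rscript
# Stage 2: derive SCS and component yields, apply the record- and cow-level
# inclusion criteria, and tabulate descriptive statistics per trait.
source("analysis/00_config.R")

rec <- read_phenotypes(file.path("results", "data", "phenotypes.csv"))
rec <- derive_traits(rec)

rf <- apply_record_filters(rec)
cf <- apply_cow_filters(rf$records)
rec <- assign_factor_levels(cf$records)

out <- res_dir("tables")
utils::write.csv(rec, file.path(out, "records_filtered.csv"),
                 row.names = FALSE)
summary <- summarize_traits(rec)
utils::write.table(summary, file.path(out, "trait_summary.tsv"),
                   sep = "\t", row.names = FALSE, quote = FALSE)
jsonlite::write_json(list(record_filters = rf$report[1:5],
                          cow_filters = cf$report[1:5]),
                     file.path(out, "filter_report.json"),
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("Records: %d -> %d after record filters; cows: %d -> %d after cow filters\n",
            rf$report$records_in, rf$report$records_out,
            cf$report$cows_in, cf$report$cows_out))
cat("Descriptive statistics (mean, SD, CV):\n")
print(summary[, c("trait", "n_records", "mean", "sd", "cv")], digits = 3)
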