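#!/usr/bin/env Rscript
# Stage 2: score every individual with HEI-2015 and the modified AHEI-2010,
# compute population-ratio mean scores, and assign weighted quintiles.

library(dietfootprint)

inputs <- read_input_tables("results/inputs")
popdata <- inputs$popdata

hei <- hei2015_score(popdata, inputs$params$hei_standards)
ahei <- ahei2010_score(popdata, inputs$params$ahei_standards, modified = TRUE)
ahei_orig <- ahei2010_score(popdata, inputs$params$ahei_standards, modified = FALSE)

scores <- dplyr::inner_join(
  tibble::tibble(id = hei$id, hei2015 = hei$total,
                 ahei2010 = ahei$total[match(hei$id, ahei$id)],
                 ahei2010_original = ahei_orig$total[match(hei$id, ahei_orig$id)]),
  popdata$records, by = "id")
scores$hei_quintile <- assign_quintiles(scores$hei2015, scores$weight)
scores$ahei_quintile <- assign_quintiles(scores$ahei2010, scores$weight)

pr_hei <- population_ratio_mean(popdata, inputs$params$hei_standards, "HEI-2015")
pr_ahei <- population_ratio_mean(popdata, inputs$params$ahei_standards, "AHEI-2010")

readr::write_csv(scores[c("id", "hei2015", "ahei2010", "ahei2010_original",
                          "hei_quintile", "ahei_quintile")],
                 "results/scores.csv")
readr::write_csv(dplyr::bind_rows(
  dplyr::mutate(pr_hei$components, index = "HEI-2015"),
  dplyr::mutate(pr_ahei$components, index = "AHEI-2010")),
  "results/population_scores.csv")

cat(sprintf("Population-ratio HEI-2015: %.1f / 100 (weighted mean of individual scores: %.1f).\n",
            pr_hei$total, with(scores, sum(hei2015 * weight) / sum(weight))))
cat(sprintf("Population-ratio AHEI-2010: %.1f / 100.\n", pr_ahei$total))
cat("Per-index weighted quintile sizes (share of weight):\n")
print(round(tapply(scores$weight, scores$hei_quintile, sum) / sum(scores$weight), 3))
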