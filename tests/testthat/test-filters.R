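test_that("quality filter retains PASS calls and traces the rest", {
  df <- data.frame(chrom = "c", pos = 1:5, ref = "C", alt = "T",
                   filter_status = c("PASS", "PASS", "LowQual", "PASS", "q10"),
                   dataset = "D", stringsAsFactors = FALSE)
  out <- quality_filter(df)
  expect_identical(nrow(out$records), 3L)
  expect_identical(out$trace$n_in, 5L)
  expect_length(out$trace$removed_keys, 2L)
  all_pass <- quality_filter(df[df$filter_status == "PASS", ])
  expect_identical(all_pass$records, df[df$filter_status == "PASS", ])
  # simulated cohort: retained fraction equals the truth PASS fraction
  sim <- simulate_cohort(test_sim_config(seed = 41))
  q <- quality_filter(sim$records_by_dataset$EXAC)
  expect_identical(nrow(q$records), sum(sim$truth$pass & !sim$truth$fp))
})

test_that("coverage filter honours thresholds and flags uncovered calls", {
  calls <- data.frame(chrom = "c", pos = 1:3, ref = "C", alt = "T",
                      dataset = "D", mean_depth = c(8, 60, 20),
                      stringsAsFactors = FALSE)
  out <- coverage_filter(calls, NULL, min_mean_depth = 15)
  expect_identical(out$calls$pos, c(2L, 3L))
  expect_identical(coverage_filter(calls, NULL, 0)$calls, calls)
  cov <- data.frame(chrom = "c", pos = c(1L, 2L), mean_depth = c(8, 60))
  out2 <- coverage_filter(calls, cov, 15)
  expect_identical(out2$calls$pos, 2L)
  expect_length(out2$trace$uncovered, 1L)  # pos 3 missing from coverage
})

test_that("concordance removes subset-unique calls but keeps shared ones", {
  mk <- function(pos, ds) data.frame(chrom = "c", pos = pos, ref = "C",
                                     alt = "T", dataset = ds,
                                     stringsAsFactors = FALSE)
  sets <- list(SUP = mk(c(1L, 2L), "SUP"),
               S1 = mk(c(1L, 3L, 9L), "S1"),
               S2 = mk(c(2L, 9L), "S2"))
  out <- concordance_filter(sets, "SUP")
  expect_identical(out$calls_by_dataset$S1$pos, c(1L, 9L))  # 3 unique: gone
  expect_identical(out$calls_by_dataset$S2$pos, c(2L, 9L))  # 9 shared: kept
  expect_identical(out$calls_by_dataset$SUP, sets$SUP)
  expect_identical(length(out$overlap[["S1&S2"]]), 1L)
  expect_error(concordance_filter(sets, NULL),
               class = "concordance_config_error")
  flagged <- concordance_filter(sets, "SUP", flag_only = TRUE)
  expect_identical(flagged$calls_by_dataset$S1$concordant, c(TRUE, FALSE, TRUE))
})

test_that("the empty pipeline emits six zero traces", {
  m <- simulate_gene_model(test_sim_config(seed = 42))
  res <- run_pipeline(list(SIM = empty_variant_frame()), m,
                      list(superset_dataset = "SIM"))
  expect_identical(nrow(res$calls), 0L)
  tt <- trace_table(res$traces)
  expect_identical(nrow(tt), 6L)
  expect_identical(tt$stage, c("quality", "annotate", "ttntv", "transcript",
                               "concordance", "coverage"))
  expect_true(all(tt$n_in == 0 & tt$n_out == 0))
})

test_that("the margin-matched fixture reproduces the published attrition", {
  fx <- make_table1_fixture()
  expect_identical(vapply(fx$calls_by_dataset, nrow, integer(1)),
                   c(EXAC = 470L, KG = 33L, ESP = 66L))
  res <- filter_annotated(fx$calls_by_dataset, fx$config)
  expect_identical(vapply(res$by_dataset, nrow, integer(1)),
                   c(EXAC = 173L, KG = 9L, ESP = 16L))
  expect_identical(vapply(res$by_dataset, carriers_from_calls, integer(1)),
                   c(EXAC = 219L, KG = 10L, ESP = 19L))
  # 247 of 470 superset calls removed at the transcript stage
  tr <- res$traces$transcript
  expect_identical(sum(startsWith(tr$removed_keys, "EXAC|")), 247L)
  # 50 more removed by coverage/concordance
  post <- c(res$traces$concordance$removed_keys, res$traces$coverage$removed_keys)
  expect_identical(sum(startsWith(post, "EXAC|")), 50L)
  # exactly three splice variants shared between the subset call sets
  expect_identical(length(res$overlap[["KG&ESP"]]), 3L)
  cmp <- compare_callsets(fx$calls_by_dataset$KG, fx$calls_by_dataset$ESP)
  kg_shared <- fx$calls_by_dataset$KG[variant_key(fx$calls_by_dataset$KG) %in%
                                        cmp$shared, ]
  expect_identical(sort(unique(kg_shared$consequence_class)), "essential_splice")
  # filtered band split of the superset role
  ex <- res$by_dataset$EXAC
  expect_identical(as.integer(table(factor(ex$band, c("Z", "I", "A", "M")))),
                   c(19L, 39L, 90L, 25L))
})

test_that("every surviving pipeline call satisfies the filter postconditions", {
  sim <- simulate_cohort(test_sim_config(seed = 43))
  cfg <- list(superset_dataset = "EXAC", coverage = sim$coverage)
  res <- run_pipeline(sim$records_by_dataset, sim$model, cfg)
  calls <- res$calls
  expect_gt(nrow(calls), 0)
  expect_true(all(is_ttntv(calls)))
  expect_true(all(calls$affects_all))
  expect_true(all(calls$exon_class == "all_transcripts"))
  expect_true(all(calls$filter_status == "PASS"))
  depth <- sim$coverage$mean_depth[match(calls$pos, sim$coverage$pos)]
  expect_true(all(depth >= 15))
  # removal accounting: removals in stages 4-6 plus finals = truncating input
  tt <- trace_table(res$traces)
  n_ttntv <- tt$n_out[tt$stage == "ttntv"]
  n_removed_late <- sum(tt$n_removed[tt$stage %in%
                                       c("transcript", "concordance", "coverage")])
  expect_equal(n_removed_late + nrow(calls), n_ttntv)
  # planted subset-unique false positives that reach the concordance stage
  # are exactly the concordance removals
  fp_keys <- sim$truth$key[sim$truth$fp]
  cc_removed <- sub("^[^|]+\\|", "", res$traces$concordance$removed_keys)
  expect_true(all(cc_removed %in% fp_keys))
})

test_that("the pipeline is order-invariant and idempotent", {
  sim <- simulate_cohort(test_sim_config(seed = 44))
  cfg <- list(superset_dataset = "EXAC", coverage = sim$coverage)
  res <- run_pipeline(sim$records_by_dataset, sim$model, cfg)
  shuffled <- lapply(sim$records_by_dataset, function(d) {
    set.seed(1); d[sample.int(nrow(d)), ]
  })
  res2 <- run_pipeline(shuffled, sim$model, cfg)
  expect_setequal(paste(res2$calls$dataset, res2$calls$key),
                  paste(res$calls$dataset, res$calls$key))
  # idempotence: re-running on the surviving records changes nothing
  again_in <- lapply(res$by_dataset, function(d) {
    d[names(sim$records_by_dataset[[1]])]
  })
  res3 <- run_pipeline(again_in, sim$model, cfg)
  expect_setequal(paste(res3$calls$dataset, res3$calls$key),
                  paste(res$calls$dataset, res$calls$key))
})

test_that("compare_callsets partitions keys exactly", {
  sim <- simulate_cohort(test_sim_config(seed = 45))
  all_calls <- sim$records_by_dataset$EXAC
  set.seed(9)
  pick <- sample(c(TRUE, FALSE), nrow(all_calls), replace = TRUE)
  a <- all_calls[pick | seq_len(nrow(all_calls)) %% 3 == 0, ]
  b <- all_calls[!pick, ]
  cmp <- compare_callsets(a, b)
  expect_setequal(c(cmp$shared, cmp$only_a), unique(variant_key(a)))
  expect_setequal(c(cmp$shared, cmp$only_b), unique(variant_key(b)))
  expect_length(intersect(cmp$only_a, cmp$only_b), 0)
  same <- compare_callsets(a, a)
  expect_length(same$only_a, 0)
  expect_length(same$only_b, 0)
  disj <- compare_callsets(a[0, ], b)
  expect_length(disj$shared, 0)
})
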