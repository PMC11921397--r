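test_that("depth filter removes samples outside mean +/- k*sd, single pass", {
  depths <- c(10, 100, 100, 100, 100, 100)
  ft <- feature_table(count_matrix(depths, 1, 6, taxa = "t1"), "read_count")
  out <- filter_samples_by_depth(ft, k = 2)
  # mean 85, sd 36.74 -> lower bound 11.5: only the depth-10 sample goes
  expect_equal(out$report$thresholds$lower, 85 - 2 * sd(depths), tolerance = 1e-6)
  expect_equal(out$report$removed_samples$sample_id, "s01")
  expect_equal(colnames(out$table$values), paste0("s0", 2:6))
  # report reconciles the dimension change
  expect_equal(out$report$dim_before[2] - nrow(out$report$removed_samples),
               out$report$dim_after[2])
})

test_that("depth filter keeps everything for equal depths and k = Inf", {
  eq <- feature_table(count_matrix(50, 2, 4), "read_count")
  expect_equal(ncol(filter_samples_by_depth(eq)$table$values), 4)
  skew <- feature_table(count_matrix(c(1, 1, 1e6, 1), 1, 4, taxa = "t1"),
                        "read_count")
  expect_equal(ncol(filter_samples_by_depth(skew, k = Inf)$table$values), 4)
  expect_error(filter_samples_by_depth(feature_table(count_matrix(1, 1, 1, taxa = "t"),
                                                     "read_count")),
               class = "qsip_data_error")
})

test_that("rare-taxon filter applies the count-in-prevalence rule", {
  # N = 100 samples: threshold is ceiling(0.02 * 100) = 2 detections
  m <- matrix(0, 3, 100, dimnames = list(c("keep2", "drop", "ubiquitous2"),
                                         sprintf("s%03d", 1:100)))
  m["keep2", 1:2] <- 3          # count 3 in exactly 2 samples -> retained
  m["drop", ] <- 2              # count 2 everywhere: never reaches 3 -> removed
  m["ubiquitous2", ] <- 5
  out <- filter_rare_taxa(feature_table(m, "read_count"))
  expect_setequal(rownames(out$table$values), c("keep2", "ubiquitous2"))
  expect_equal(out$report$removed_taxa$taxon_id, "drop")
  expect_equal(out$report$thresholds$min_samples, 2)

  # N = 50: threshold ceiling(1) = 1, a single strong detection suffices
  m2 <- matrix(0, 2, 50, dimnames = list(c("once", "anchor"), sprintf("s%02d", 1:50)))
  m2["once", 7] <- 5
  m2["anchor", ] <- 4
  out2 <- filter_rare_taxa(feature_table(m2, "read_count"))
  expect_true("once" %in% rownames(out2$table$values))
})

test_that("relative-abundance transform normalizes columns and rejects empties", {
  m <- count_matrix(c(2, 3, 5), 3, 1)
  rel <- to_relative_abundance(feature_table(m, "read_count"))
  expect_equal(unname(rel$values[, 1]), c(0.2, 0.3, 0.5))
  expect_identical(rel$unit, "relative_abundance")
  one <- to_relative_abundance(feature_table(count_matrix(7, 1, 1, taxa = "t"),
                                             "read_count"))
  expect_equal(unname(one$values[1, 1]), 1)
  bad <- count_matrix(c(1, 2, 0, 0), 2, 2)
  expect_error(to_relative_abundance(feature_table(bad, "read_count")), "s02",
               class = "qsip_data_error")
})

test_that("QSEQ normalization scales columns to the qPCR totals", {
  m <- count_matrix(c(1, 3, 0, 4), 2, 2)
  rel <- to_relative_abundance(feature_table(m, "read_count"))
  qp <- data.frame(sample_id = c("s01", "s02"), copies_per_ng_dna = c(2000, 800))
  out <- qseq_normalize(rel, qp)
  expect_equal(out$table$values["t01", "s01"], 0.25 * 2000)
  expect_identical(out$table$unit, "copies_per_ng_dna")
  # column sums equal the qPCR totals; ratios preserved; nothing negative
  expect_equal(unname(colSums(out$table$values)), qp$copies_per_ng_dna)
  expect_equal(out$table$values[1, 1] / out$table$values[2, 1],
               rel$values[1, 1] / rel$values[2, 1])
  expect_true(all(out$table$values >= 0))
  # zero relative abundance stays zero
  expect_equal(out$table$values["t01", "s02"], 0)
})

test_that("samples without qPCR records are dropped with a report entry", {
  m <- count_matrix(1:6, 2, 3)
  rel <- to_relative_abundance(feature_table(m, "read_count"))
  qp <- data.frame(sample_id = c("s01", "s03"), copies_per_ng_dna = c(100, 300))
  out <- qseq_normalize(rel, qp)
  expect_equal(colnames(out$table$values), c("s01", "s03"))
  expect_equal(out$report$removed_samples$sample_id, "s02")
  expect_match(out$report$removed_samples$reason, "qPCR")
})

test_that("sequential filtering accounting reconciles across steps", {
  set.seed(42)
  m <- count_matrix(rpois(20 * 30, 40), 20, 30)
  m[, 1] <- 0; m[1, 1] <- 2            # starved sample
  m[15, ] <- rbinom(30, 1, 0.03) * 2   # rare taxon
  ft <- feature_table(m, "read_count")
  f1 <- filter_samples_by_depth(ft)
  f2 <- filter_rare_taxa(f1$table)
  expect_equal(f1$report$dim_after, f2$report$dim_before)
  expect_equal(nrow(f2$table$values),
               20 - nrow(f2$report$removed_taxa))
  expect_equal(ncol(f2$table$values),
               30 - nrow(f1$report$removed_samples))
  # retained and removed sets are disjoint
  expect_length(intersect(rownames(f2$table$values),
                          f2$report$removed_taxa$taxon_id), 0)
})
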