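make_profile_fixture <- function() {
  # two 13C cores + one 12C core, three density groups each
  samples <- c(outer(c("13C_c1", "13C_c2", "12C_c1"),
                     c("light", "medium", "heavy"), paste, sep = "_"))
  v <- matrix(0, 3, length(samples),
              dimnames = list(c("a1", "a2", "b1"), samples))
  # genus X members a1, a2; genus Y member b1
  # per-sample values (light, medium, heavy) per core:
  for (cid in c("13C_c1", "13C_c2", "12C_c1")) {
    v["a1", paste(cid, c("light", "medium", "heavy"), sep = "_")] <- c(100, 5, 10)
    v["a2", paste(cid, c("light", "medium", "heavy"), sep = "_")] <- c(0, 3, 2)
    v["b1", paste(cid, c("light", "medium", "heavy"), sep = "_")] <- c(50, 1, 1)
  }
  v["a1", "13C_c2_heavy"] <- 30   # cores differ: genus X totals 15 vs 35
  meta <- do.call(rbind, lapply(strsplit(samples, "_(?=[^_]+$)", perl = TRUE),
                                function(p) {
    data.frame(sample_id = paste(p[1], p[2], sep = "_"), core_id = p[1],
               wetland = "natural", redox = "anoxic",
               isotope = sub("_c\\d$", "", p[1]),
               density = c(light = 1.67, medium = 1.72, heavy = 1.775)[p[2]],
               density_group = p[2], stringsAsFactors = FALSE)
  }))
  tax <- data.frame(taxon_id = c("a1", "a2", "b1"),
                    phylum = c("P1", "P1", "P2"),
                    genus = c("X", "X", "Y"))
  list(table = feature_table(v, "copies_per_ng_dna", taxonomy = tax),
       metadata = meta)
}

test_that("active totals sum heavy+medium of labeled cores at genus level", {
  fx <- make_profile_fixture()
  prof <- total_active_abundance(fx$table, fx$metadata, active = c("a1", "a2"))
  x <- prof[prof$taxon == "X", ]
  # core 13C_c1: a1 5+10 + a2 3+2 = 20 ; core 13C_c2: a1 5+30 + a2 5 = 40
  # light (100) is excluded throughout
  expect_equal(x$mean, 30)
  expect_equal(x$n_cores, 2)
  expect_equal(x$sd, sd(c(20, 40)))
  expect_equal(x$se, sd(c(20, 40)) / sqrt(2))
  expect_identical(x$phylum, "P1")
  # genus totals conserve the member-ASV totals
  pc <- attr(prof, "per_core")[["natural / anoxic"]]
  expect_equal(sum(pc), 20 + 40)
  # inactive genus Y is absent
  expect_false("Y" %in% prof$taxon)
})

test_that("cores missing requested groups contribute zero with a note", {
  fx <- make_profile_fixture()
  keep <- fx$metadata$sample_id != "13C_c1_medium"
  tab <- feature_table(fx$table$values[, fx$metadata$sample_id[keep]],
                       "copies_per_ng_dna", taxonomy = fx$table$taxonomy)
  expect_message(
    prof <- total_active_abundance(tab, fx$metadata[keep, ], active = c("a1", "a2")),
    "missing density group")
  # 13C_c1 now contributes only heavy: a1 10 + a2 2 = 12
  expect_equal(prof$mean[prof$taxon == "X"], mean(c(12, 40)))
})

test_that("background abundance spans all groups and both isotopes", {
  fx <- make_profile_fixture()
  prof <- background_abundance(fx$table, fx$metadata, active = "a1")
  # every core carries a1 = 115 except 13C_c2 (100+5+30 = 135)
  x12 <- prof[prof$isotope == "12C" & prof$taxon == "X", ]
  x13 <- prof[prof$isotope == "13C" & prof$taxon == "X", ]
  expect_equal(x12$mean, 115)
  expect_equal(x13$mean, mean(c(115, 135)))
  # single-core group reports missing dispersion, not zero
  expect_true(is.na(x12$sd))
})

test_that("active sets can come straight from a fit, per treatment group", {
  hx <- hand_experiment()
  fit <- qsip(hx$table, hx$metadata, n_draws = 100, seed = 8)
  prof <- total_active_abundance(hx$table, hx$metadata, fit, rank = "genus")
  # only t1 is active; it carries 10 copies in the heavy group per 13C core
  expect_equal(prof$mean, 10)
  expect_equal(prof$taxon, "t1")  # no taxonomy: ASV id is the label
})

test_that("Shannon diversity matches closed forms", {
  expect_equal(shannon_diversity(rep(1, 4)), log(4))
  expect_equal(shannon_diversity(c(0, 7, 0)), 0)
  expect_equal(shannon_diversity(c(0.5, 0.5)), log(2))
  expect_error(shannon_diversity(c(0, 0)), class = "qsip_data_error")
  expect_error(shannon_diversity(c(-1, 2)), class = "qsip_data_error")
  # uniform maximizes H at ln S
  set.seed(9)
  for (i in 1:20) {
    x <- rgamma(6, 2)
    expect_lte(shannon_diversity(x), log(6) + 1e-12)
  }
  # per-core H from a community profile
  fx <- make_profile_fixture()
  prof <- total_active_abundance(fx$table, fx$metadata, active = c("a1", "a2", "b1"))
  h <- shannon_diversity(prof)
  expect_equal(nrow(h), 2)
  # core 13C_c1: X = 20, Y = 2 -> H of (20, 2)
  p <- c(20, 2) / 22
  expect_equal(h$shannon[h$core_id == "13C_c1"], -sum(p * log(p)))
})

test_that("overlap partitions are disjoint, exhaustive and hand-checkable", {
  ov <- overlap_partition(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(ov$count[ov$region == "A"], 1)
  expect_equal(ov$count[ov$region == "B"], 1)
  expect_equal(ov$count[ov$region == "A&B"], 2)
  members <- attr(ov, "members")
  expect_setequal(members[["A&B"]], c("b", "c"))
  # identical sets: everything lands in the full intersection
  ov2 <- overlap_partition(list(X = letters[1:5], Y = letters[1:5]))
  expect_equal(ov2$count[ov2$region == "X&Y"], 5)
  expect_equal(sum(ov2$count), 5)
  # random 5-set systems: regions disjoint, counts sum to the union
  set.seed(13)
  for (i in 1:10) {
    sets <- replicate(5, sample(sprintf("t%02d", 1:40), 20), simplify = FALSE)
    names(sets) <- LETTERS[1:5]
    ov3 <- overlap_partition(sets)
    members <- attr(ov3, "members")
    expect_equal(sum(ov3$count), length(unique(unlist(sets))))
    expect_equal(anyDuplicated(unlist(members)), 0)
    expect_equal(nrow(ov3), 2^5 - 1)
  }
  expect_error(overlap_partition(list(A = "x", A = "y")), class = "qsip_data_error")
})
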