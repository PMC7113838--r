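test_that("the candidate filter applies rarity, absence and deleteriousness", {
  crit <- filter_criteria()
  # rare everywhere, absent, unanimously damaging
  expect_true(qualify_variant(vrow("s1", "G1", freqs = rep(0.004, 4)), crit))
  # one panel at 0.6%
  expect_false(qualify_variant(vrow("s2", "G1",
                                    freqs = c(0.006, 0, 0, 0)), crit))
  # boundary: 0.5% exactly fails the strict < rule
  expect_false(qualify_variant(vrow("s3", "G1",
                                    freqs = c(0.005, 0, 0, 0)), crit))
  # present in the Chinese reference subset
  expect_false(qualify_variant(vrow("s4", "G1", chinese = TRUE), crit))
  expect_true(qualify_variant(
    vrow("s4", "G1", chinese = TRUE),
    filter_criteria(require_absent_chinese_panel = FALSE)))
  # deleteriousness consensus
  half <- vrow("s5", "G1", flags = c(TRUE, TRUE, FALSE, FALSE))
  expect_false(qualify_variant(half, crit))
  expect_false(qualify_variant(half, filter_criteria(deleterious_rule = "majority")))
  expect_true(qualify_variant(half, filter_criteria(deleterious_rule = "any")))
  # splice variants are deleterious by consequence class
  expect_true(qualify_variant(vrow("s6", "G1", flags = rep(FALSE, 4),
                                   consequence = "splice"), crit))
  # missing panel frequency treated as absent, with a warning
  expect_warning(
    expect_true(qualify_variant(vrow("s7", "G1",
                                     freqs = c(NA, 0, 0, 0)), crit)),
    "missing panel frequencies")
  expect_error(filter_criteria(deleterious_rule = "plurality"),
               class = "pahburden_config_error")
})

test_that("discover_candidates matches an exhaustive brute-force oracle", {
  cfg <- small_config(seed = 21, n_discovery_cases = 20L,
                      n_replication_cases = 5L, n_controls = 25L,
                      background_hit_rate = 4, background_reject_rate = 3,
                      n_common_snps = 40L)
  co <- generate_cohort(cfg)
  expect_lte(nrow(co$subjects), 50)
  expect_lte(nrow(co$variants), 250)
  cases <- co$subjects$subject_id[co$subjects$group == "case"]
  for (rule in c("all", "any")) {
    crit <- filter_criteria(deleterious_rule = rule)
    got <- suppressWarnings(discover_candidates(co, crit))$pairs
    want <- suppressWarnings(brute_force_candidates(co, crit, cases))
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = paste("rule", rule))
  }
})

test_that("tightening the filter never enlarges the candidate set", {
  co <- generate_cohort(small_config(seed = 22))
  key <- function(p) paste(p$subject_id, p$site_id)
  loose <- discover_candidates(co, filter_criteria(maf_max = 0.005,
                                                   deleterious_rule = "any"))
  tighter_maf <- discover_candidates(co, filter_criteria(maf_max = 0.0005,
                                                         deleterious_rule = "any"))
  tighter_rule <- discover_candidates(co, filter_criteria(maf_max = 0.005,
                                                          deleterious_rule = "all"))
  expect_true(all(key(tighter_maf$pairs) %in% key(loose$pairs)))
  expect_true(all(key(tighter_rule$pairs) %in% key(loose$pairs)))
  # degenerate threshold: nothing is rarer than everything
  expect_equal(nrow(discover_candidates(co, filter_criteria(maf_max = 1e-12))$pairs), 0)
})

test_that("carriers are counted per subject and homozygotes are excluded", {
  v <- rbind(vrow("g1a", "G1"), vrow("g1b", "G1"), vrow("g2a", "G2"))
  G <- matrix(0L, 3, 3, dimnames = list(c("P1", "P2", "P3"), v$site_id))
  G["P1", c("g1a", "g1b")] <- 1L   # two qualifying variants, one gene
  G["P2", "g1a"] <- 1L
  G["P3", "g2a"] <- 2L             # homozygous-alt: not a dominant carrier
  co <- manual_cohort(v, G)
  map <- discover_candidates(co)
  expect_equal(nrow(map$pairs), 3)
  expect_equal(map$carrier_counts[["G1"]], 2)  # P1 counted once
  expect_false("G2" %in% names(map$carrier_counts))
})

test_that("genotyped sites missing from the variant table are an error", {
  v <- vrow("s1", "G1")
  G <- matrix(0L, 1, 2, dimnames = list("P1", c("s1", "mystery")))
  expect_error(discover_candidates(manual_cohort(v, G)),
               class = "pahburden_data_error")
})

test_that("gene prioritization thresholds, orders, and flags expression", {
  v <- rbind(vrow("a1", "GA"), vrow("b1", "GB"), vrow("c1", "GC"),
             vrow("d1", "GD"))
  G <- matrix(0L, 5, 4,
              dimnames = list(paste0("P", 1:5), v$site_id))
  G[1:4, "a1"] <- 1L          # GA: 4 carriers
  G[1:3, "b1"] <- 1L          # GB: 3 carriers
  G[c(1, 2), "c1"] <- 1L      # GC: 2 carriers -> dropped
  G[2:4, "d1"] <- 1L          # GD: 3 carriers, ties with GB on count
  expr <- data.frame(gene = c("GA", "GB", "GC"),
                     tissues = c("lung;heart", "liver", "lung"),
                     stringsAsFactors = FALSE)
  co <- manual_cohort(v, G, expression = expr)
  map <- discover_candidates(co)
  pri <- NULL
  expect_warning(pri <- prioritize_genes(map, filter_criteria(), expr), "GD")
  expect_equal(pri$gene, c("GA", "GB", "GD"))  # count desc, ties by symbol
  expect_equal(pri$expressed, c(TRUE, FALSE, FALSE))
  # everything below threshold -> empty list
  pri5 <- prioritize_genes(map, filter_criteria(min_shared_carriers = 5L),
                           expr)
  expect_equal(nrow(pri5), 0)
})

test_that("the planted gene is recovered with few expressed background genes", {
  # 60 seeds at the default carrier frequencies, arm sizes, and background
  # rates (kinship SNPs scaled down; they do not enter discovery)
  n_seeds <- 60
  recovered <- logical(n_seeds)
  fp_counts <- new.env()
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(simulation_config(seed = 3000 + s,
                                            n_common_snps = 20L))
    pri <- prioritize_genes(discover_candidates(co), filter_criteria(),
                            co$expression)
    final <- pri$gene[pri$expressed]
    recovered[s] <- co$config$causal_gene %in% final
    for (g in setdiff(final, co$config$causal_gene))
      assign(g, (get0(g, fp_counts) %||% 0L) + 1L, fp_counts)
  }
  expect_gte(mean(recovered), 0.95)
  # no individual background gene qualifies in more than 5% of seeds
  fp <- unlist(as.list(fp_counts))
  if (length(fp)) expect_lte(max(fp) / n_seeds, 0.05)
})

test_that("the known-PAH-gene screen flags rare deleterious hits only", {
  v <- rbind(vrow("bmpr2_rare", "BMPR2"),
             vrow("bmpr2_common", "BMPR2", freqs = rep(0.02, 4)),
             vrow("other", "SOMEGENE"))
  G <- matrix(0L, 3, 3, dimnames = list(c("P1", "P2", "P3"), v$site_id))
  G["P1", "bmpr2_rare"] <- 1L
  G["P2", "bmpr2_common"] <- 1L
  G["P3", "other"] <- 1L
  co <- manual_cohort(v, G)
  hits <- screen_known_pah_genes(co)
  expect_equal(hits$subject_id, "P1")
  expect_equal(hits$gene, "BMPR2")
  expect_error(screen_known_pah_genes(co, gene_list = character(0)),
               class = "pahburden_config_error")
  expect_length(pah_gene_panel(), 17)
})
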