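test_that("pairwise divergence reproduces the published worked examples", {
  refs16 <- synthetic_haplotype_refs("16S")
  d16 <- pairwise_divergence(refs16[["t"]], refs16[["z2"]])
  expect_equal(d16$site_differences, 6)
  expect_equal(d16$sites_compared, 481)
  expect_equal(d16$percent, 1.25)
  refscb <- synthetic_haplotype_refs("cytb")
  dcb <- pairwise_divergence(refscb[["22"]], refscb[["37"]])
  expect_equal(dcb$site_differences, 6)
  expect_equal(dcb$percent, 1.21)
  expect_equal(pairwise_divergence("ACGT", "ACGT")$percent, 0)
  # ambiguous sites drop out of numerator and denominator
  d <- pairwise_divergence("ACGTN", "ACCT-")
  expect_equal(d$site_differences, 1)
  expect_equal(d$sites_compared, 4)
  expect_error(pairwise_divergence("ACG", "ACGT"), "alignment")
})

test_that("haplotype assignment finds exact, novel and ambiguous matches", {
  refs <- synthetic_haplotype_refs("16S")[c("t", "z")]
  hit <- assign_haplotype(refs[["t"]], refs)
  expect_equal(hit$name, "t")
  expect_equal(hit$distance, 0)
  expect_false(hit$novel)
  # the z2 sequence is one substitution from z: novel variant, suggested name
  z2 <- synthetic_haplotype_refs("16S")[["z2"]]
  novel <- assign_haplotype(z2, refs)
  expect_equal(novel$name, "z")
  expect_equal(novel$distance, 1)
  expect_true(novel$novel)
  expect_equal(novel$suggested_name, "z2")
  # equidistant query is flagged ambiguous with both candidates
  amb <- assign_haplotype("AAAA", c(x = "AAAT", y = "AAAC"))
  expect_true(amb$ambiguous)
  expect_setequal(amb$candidates, c("x", "y"))
  expect_error(assign_haplotype("AAAA", character(0)), "configuration")
})

test_that("genotype encoding follows the alphabetical dosage-agnostic rule", {
  expect_equal(encode_genotype(list(c("G", "A"))), "AG")
  expect_equal(encode_genotype(list("T")), "TT")
  expect_equal(encode_genotype(list("A/G", "T", "?")), "AGTT??")
  expect_equal(encode_genotype(list(c("C", "T"), "G")), "CTGG")
  expect_error(encode_genotype(list(c("A", "C", "G"))), "ploidy")
  # stable under within-pair allele order permutation
  expect_equal(encode_genotype(list(c("T", "C"))),
               encode_genotype(list(c("C", "T"))))
  # decode inverts encode
  calls <- c("A", "A/G", "?", "T")
  expect_equal(decode_genotype(encode_genotype(as.list(calls))), calls)
})

test_that("the published genotype table expands and encodes correctly", {
  t2 <- table2_fixture()
  expect_equal(nrow(t2$table), 10)
  expect_length(t2$loci, 16)
  expect_true(all(nchar(t2$encoded) == 32))
  # genotype 1 carries 9 heterozygous loci
  calls1 <- decode_genotype(t2$encoded[["1"]])
  expect_equal(sum(grepl("/", calls1)), 9)
  # genotypes 8 and 10 each carry exactly two missing loci
  for (g in c("8", "10"))
    expect_equal(sum(decode_genotype(t2$encoded[[g]]) == "?"), 2)
  expect_equal(unname(t2$haplotype[c("1", "9")]), c("t/22", "z2/37"))
})

test_that("genotype distances reproduce the published counts", {
  t2 <- table2_fixture()
  enc <- t2$encoded
  expect_equal(mlg_distance(enc[["9"]], enc[["10"]]), 3)
  expect_equal(mlg_distance(enc[["1"]], enc[["2"]]), 1)
  d_to_1 <- vapply(as.character(2:7), function(g)
    mlg_distance(enc[["1"]], enc[[g]]), numeric(1))
  expect_equal(max(d_to_1), 2)
  for (g in names(enc)) expect_equal(mlg_distance(enc[[g]], enc[[g]]), 0)
  # symmetry
  expect_equal(mlg_distance(enc[["1"]], enc[["9"]]),
               mlg_distance(enc[["9"]], enc[["1"]]))
})

test_that("pairwise deletion keeps genotypes distinct that column masking merges", {
  t2 <- table2_fixture()
  # genotypes 1 and 7 differ at loci that carry '?' in other genotypes;
  # pairwise deletion must still see their difference
  expect_gt(mlg_distance(t2$encoded[["1"]], t2$encoded[["7"]]), 0)
})

test_that("collapsing individuals to genotypes is idempotent and ordered by abundance", {
  t2 <- table2_fixture()
  set.seed(40)
  counts <- c(280, 30, 25, 20, 15, 10, 4, 6, 26, 9)
  cohort <- rep(unname(t2$encoded), counts)[sample(sum(counts))]
  mlg <- collapse_mlg(cohort)
  expect_equal(nrow(mlg$genotypes), 10)
  expect_equal(mlg$genotypes$count, sort(counts, decreasing = TRUE))
  expect_equal(mlg$genotypes$encoded[1], unname(t2$encoded[["1"]]))
  # idempotence: collapsing the collapsed set changes nothing
  again <- collapse_mlg(mlg$genotypes$encoded)
  expect_equal(again$genotypes$encoded, mlg$genotypes$encoded)
  expect_true(all(again$genotypes$count == 1))
  # 3 identical strings -> one genotype of count 3
  one <- collapse_mlg(rep("AATT", 3))
  expect_equal(nrow(one$genotypes), 1)
  expect_equal(one$genotypes$count, 3)
  two <- collapse_mlg(c("AATT", "AATG"))
  expect_equal(nrow(two$genotypes), 2)
  # missing symbol is a distinct literal
  expect_equal(nrow(collapse_mlg(c("AA??", "AATT"))$genotypes), 2)
})

test_that("median-joining network handles singletons and small star cases", {
  single <- median_joining_network("AATT")
  expect_equal(nrow(single$nodes), 1)
  expect_equal(nrow(single$edges), 0)
  t2 <- table2_fixture()
  enc <- t2$encoded
  # {g1, g2, g4}: distances 1, 1, 2 -> star centred on g1, no medians
  star <- median_joining_network(unname(enc[c("1", "2", "4")]),
                                 labels = c("1", "2", "4"))
  expect_equal(nrow(star$nodes), 3)
  expect_equal(nrow(star$edges), 2)
  expect_true(all(star$edges$weight == 1))
  hub <- star$nodes$label[which.max(tabulate(c(star$edges$from,
                                               star$edges$to), 3))]
  expect_equal(hub, "1")
  expect_equal(sum(star$nodes$type == "median"), 0)
})

test_that("epsilon-zero networks on tree-like subsets match a brute-force MST", {
  t2 <- table2_fixture()
  subsets <- list(c("1", "2", "3", "4"), c("1", "2", "4", "5", "6"),
                  c("1", "3", "7", "9", "10"),
                  c("1", "2", "3", "4", "5", "6"))
  for (ss in subsets) {
    enc <- unname(t2$encoded[ss])
    net <- median_joining_network(enc, labels = ss)
    obs <- net$nodes$type == "observed"
    if (all(obs) && nrow(net$edges) == length(ss) - 1L) {
      D <- outer(seq_along(enc), seq_along(enc),
                 Vectorize(function(i, j) mlg_distance(enc[i], enc[j])))
      expect_equal(sum(net$edges$weight), prim_mst_weight(D))
    }
  }
})

test_that("the full published genotype set yields a connected network centred on genotype 1", {
  t2 <- table2_fixture()
  net <- median_joining_network(unname(t2$encoded), labels = names(t2$encoded))
  expect_true(all(names(t2$encoded) %in% net$nodes$label))
  g <- as_igraph(net)
  expect_true(igraph::is_connected(g))
  expect_true(all(net$edges$weight >= 1))
  # median vectors, if any, have degree >= 3
  deg <- tabulate(c(net$edges$from, net$edges$to), nbins = nrow(net$nodes))
  expect_true(all(deg[net$nodes$type == "median"] >= 3))
  # genotype 1 attains the maximum degree among observed freshwater nodes
  fresh <- which(net$nodes$type == "observed" &
                 net$nodes$label %in% as.character(1:8))
  expect_equal(max(deg[fresh]),
               deg[which(net$nodes$label == "1")])
})

test_that("FASTA round trip preserves haplotype references", {
  refs <- synthetic_haplotype_refs("16S")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_haplotypes(refs, path)
  back <- read_haplotypes(path)
  expect_equal(back, refs)
})

test_that("genotype tables encode row-wise and survive CSV round trips", {
  t2 <- table2_fixture()
  tab <- data.frame(specimen_id = c("s1", "s2"), site_id = c("A", "A"),
                    rbind(decode_genotype(t2$encoded[["1"]]),
                          decode_genotype(t2$encoded[["9"]])),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("specimen_id", "site_id", t2$loci)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  geno <- read_genotype_csv(path)
  enc <- encode_genotype_table(geno)
  expect_equal(unname(enc), unname(t2$encoded[c("1", "9")]))
})
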