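test_that("marginal reconstruction equals exhaustive enumeration", {
  tr <- tree4()
  trait <- c(A = 1, B = 0, C = 1, D = NA)
  Q <- hidden_rate_matrix(random_rates(14))
  asr <- marginal_asr(tr, trait, Q)
  ntip <- 4
  for (node in (ntip + 1):(ntip + tr$Nnode)) {
    expect_equal(unname(asr$probs[node, ]),
                 enum_marginal(tr, trait, Q, node), tolerance = 1e-9)
  }
  expect_equal(unname(rowSums(asr$probs)), rep(1, ntip + tr$Nnode),
               tolerance = 1e-9)
})

test_that("marginal identity: down x up partials reproduce the likelihood at every node", {
  tr <- tree6()
  trait <- c(A = 1, B = 1, C = 0, D = NA, E = 0, F = 1)
  Q <- hidden_rate_matrix(random_rates(15))
  asr <- marginal_asr(tr, trait, Q)
  ll <- pruning_loglik(tr, trait, Q)
  expect_equal(asr$loglik, ll, tolerance = 1e-12)
  expect_equal(asr$log_joint, rep(ll, length(asr$log_joint)),
               tolerance = 1e-9)
})

test_that("observed tips keep their observed projection; p_present is consistent", {
  tr <- tree5()
  trait <- c(A = 1, B = 0, C = 1, D = NA, E = 0)
  Q <- hidden_rate_matrix(random_rates(16))
  asr <- marginal_asr(tr, trait, Q)
  expect_equal(unname(asr$probs[1, "1S"] + asr$probs[1, "1F"]), 1,
               tolerance = 1e-12)
  expect_equal(unname(asr$probs[2, "0S"] + asr$probs[2, "0F"]), 1,
               tolerance = 1e-12)
  expect_equal(asr$p_present,
               unname(asr$probs[, "1S"] + asr$probs[, "1F"]))
  expect_true(all(asr$p_present >= 0 & asr$p_present <= 1))
})

test_that("all-present data with near-zero loss reconstructs presence at the root", {
  taxo <- read_taxonomy(text = "((A,B,C,D),(E,F,G,H));")
  tr <- sample_trees(taxo, 1, seed = 19)$trees[[1]]
  trait <- setNames(rep(1, 8), tr$tip.label)
  Q <- hidden_rate_matrix(rate_vec(0.2, 1e-10, 0.2, 1e-10,
                                   0.1, 0.1, 0.1, 0.1))
  asr <- marginal_asr(tr, trait, Q)
  expect_gt(asr$p_present[9], 0.95)   # root node ntip+1
})

test_that("family root presence is read at the family MRCA", {
  taxo <- read_taxonomy(text = "((A,B,C),(D,E));")
  post <- sample_trees(taxo, 5, seed = 23)
  fams <- setNames(c("X", "X", "X", "Y", "Y"), c("A", "B", "C", "D", "E"))
  trait <- c(A = 1, B = 1, C = 1, D = 0, E = 0)
  Q <- hidden_rate_matrix(rate_vec(0.3, 0.1, 0.3, 0.1, 0.2, 0.2, 0.2, 0.2))
  for (tr in post$trees) {
    asr <- marginal_asr(tr, trait, Q)
    node <- ape::getMRCA(tr, c("A", "B", "C"))
    expect_equal(family_root_presence(asr, "X", fams),
                 asr$p_present[node])
    # X's tips are all present with slow loss: high p at the family root
    expect_gt(family_root_presence(asr, "X", fams), 0.5)
  }
  asr1 <- marginal_asr(post$trees[[1]], trait, Q)
  expect_error(family_root_presence(asr1, "Z", fams), "fewer than 2")
})

test_that("reconstructability bands partition and nest correctly", {
  probs <- matrix(c(1, 0.96, 0.8, 0.5, 0.2, 0.02,
                    0.97, 0.7, 0.6, 0.3, 0.1, 0.01), ncol = 2,
                  dimnames = list(paste0("F", 1:6), c("famA", "famB")))
  rec <- reconstructability_summary(probs)
  pf <- rec$per_family
  expect_equal(pf$present_95, c(2 / 6, 1 / 6))
  expect_equal(pf$present_75, c(3 / 6, 1 / 6))   # nested: 0.96 in both
  expect_equal(pf$absent_05, c(1 / 6, 1 / 6))
  expect_equal(pf$absent_25, c(2 / 6, 2 / 6))
  # five exclusive bands partition every column
  for (fam in colnames(probs))
    expect_equal(sum(table(rec$bands[, fam])), 6)
  expect_equal(pf$present_95 + (pf$present_75 - pf$present_95) +
                 pf$uncertain + (pf$absent_25 - pf$absent_05) +
                 pf$absent_05, rep(1, 2))
  # uniform probabilities: about half the mass in the uncertain band
  set.seed(4)
  u <- matrix(runif(1000), ncol = 1, dimnames = list(NULL, "f"))
  ru <- reconstructability_summary(u)
  expect_lt(abs(ru$per_family$uncertain - 0.5), 0.06)
  expect_error(reconstructability_summary(probs * 2), "\\[0, 1\\]")
})

test_that("category normalization removes category-size effects", {
  feats <- paste0("F", 1:55)
  catalog <- data.frame(feature = feats,
                        functional_category = rep(c("negation", "deixis"),
                                                  c(5, 50)),
                        domain = "clause", part_of_speech = "verb")
  probs <- matrix(0, 55, 1, dimnames = list(feats, "famA"))
  probs[c(1, 2), 1] <- 1          # 2 of 5 negation features
  probs[6:25, 1] <- 1             # 20 of 50 deixis features
  out <- category_normalized_reconstruction(probs, catalog,
                                            "functional_category")
  expect_equal(out$proportion[out$category == "negation"], 0.4)
  expect_equal(out$proportion[out$category == "deixis"], 0.4)
  expect_equal(out$n_reconstructed[out$category == "negation"], 2)
})

test_that("pairwise family overlap percentage follows the stated formula", {
  feats <- paste0("F", 1:10)
  probs <- matrix(0, 10, 2, dimnames = list(feats, c("A", "B")))
  probs[1:4, "A"] <- 0.99
  probs[3:6, "B"] <- 0.99
  ovl <- pairwise_family_overlap(probs)
  expect_equal(ovl$percent["A", "B"], 20)   # shared {F3,F4} out of 10
  expect_equal(ovl$counts["A", "B"], 2)
  expect_true(is.na(ovl$percent["A", "A"]))
  # identical sets: off-diagonal equals either family's own percentage
  probs2 <- probs; probs2[, "B"] <- probs2[, "A"]
  expect_equal(pairwise_family_overlap(probs2)$percent["A", "B"], 40)
  # disjoint sets
  probs3 <- probs; probs3[, "B"] <- 0; probs3[7:8, "B"] <- 1
  expect_equal(pairwise_family_overlap(probs3)$percent["A", "B"], 0)
})

test_that("proto-child distances count differing observed features", {
  vals <- matrix("present", 4, 5,
                 dimnames = list(c("t1", "t2", "t3", "t4"),
                                 paste0("F", 1:5)))
  vals["t2", c("F1", "F2", "F3")] <- "absent"
  vals["t3", "F4"] <- "missing"
  vals["t4", ] <- "absent"
  fm <- feature_matrix(vals, setNames(c("X", "X", "X", "Y"),
                                      rownames(vals)))
  root_probs <- setNames(c(0.99, 0.99, 0.99, 0.99, 0.5), paste0("F", 1:5))
  pcd <- proto_child_distance(root_probs, fm, "X")
  expect_equal(pcd$n_reconstructed, rep(4, 3))  # F5 below threshold
  expect_equal(pcd$n_differ[pcd$taxon == "t1"], 0)
  expect_equal(pcd$n_differ[pcd$taxon == "t2"], 3)
  expect_equal(pcd$n_differ[pcd$taxon == "t3"], 0)
  expect_equal(pcd$n_missing[pcd$taxon == "t3"], 1)
  # brute-force tally over the whole table
  feats <- paste0("F", 1:4)
  for (tx in c("t1", "t2", "t3")) {
    expect_equal(pcd$n_differ[pcd$taxon == tx],
                 sum(vals[tx, feats] == "absent"))
  }
})
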