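make_assignment <- function(n1 = 7, n2 = 4) {
  labels <- setNames(rep(c("CL1", "CL2"), c(n1, n2)),
                     sprintf("S%02d", seq_len(n1 + n2)))
  structure(list(labels = labels, k = 2), class = "ClusterAssignment")
}

test_that("k = 1 Hotelling reduces exactly to the pooled two-sided t-test", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(11)
    X <- matrix(x, 11, 1)
    h <- pprnet:::hotelling_core(X, 1:7, 8:11, variance_kept = 0.90)
    tt <- t.test(x[1:7], x[8:11], var.equal = TRUE)
    expect_equal(h$k, 1L)
    expect_equal(h$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(h$p, tt$p.value, tolerance = 1e-10)
  }
})

test_that("identical group means give T2 = 0, F = 0, p = 1", {
  # zero-variance input: test skipped by convention
  X0 <- matrix(rep(c(1, 2, 3), each = 11), 11, 3)
  h0 <- pprnet:::hotelling_core(X0, 1:7, 8:11)
  expect_equal(h0$p, 1)
  expect_equal(h0$T2, 0)
  # variance present but both group means are exactly zero: each group is
  # built from +/- pairs, so the mean difference vanishes in every PC
  set.seed(8)
  a <- rnorm(2); b <- rnorm(2); c <- rnorm(2); d <- rnorm(2)
  X <- rbind(a, -a, b, -b, rep(0, 2),  # group 1 (5 rows, mean 0)
             c, -c, d, -d, rep(0, 2), rep(0, 2)) # group 2 (6 rows, mean 0)
  h <- pprnet:::hotelling_core(X, 1:5, 6:11)
  expect_equal(h$T2, 0, tolerance = 1e-12)
  expect_equal(h$p, 1, tolerance = 1e-6)
})

test_that("k is capped at n1 + n2 - 2 and at the 90% variance target", {
  set.seed(5)
  X <- matrix(rnorm(11 * 30), 11, 30)
  h <- pprnet:::hotelling_core(X, 1:7, 8:11, variance_kept = 0.90)
  expect_lte(h$k, 9)
  X1 <- cbind(rnorm(11), rnorm(11, sd = 1e-6))
  h1 <- pprnet:::hotelling_core(X1, 1:7, 8:11, variance_kept = 0.90)
  expect_equal(h1$k, 1L)
})

test_that("Hotelling type-I error is calibrated under the null", {
  set.seed(202)
  reps <- 500 # the 2000-rep version runs in the acceptance suite
  p5 <- 0; p1 <- 0
  for (i in seq_len(reps)) {
    X <- matrix(rnorm(11 * 8), 11, 8)
    p <- pprnet:::hotelling_core(X, 1:7, 8:11)$p
    p5 <- p5 + (p < 0.05)
    p1 <- p1 + (p < 0.01)
  }
  expect_gt(p5 / reps, 0.03)
  expect_lt(p5 / reps, 0.075)
  expect_lt(p1 / reps, 0.025)
})

test_that("rejection rate grows with the planted effect size", {
  set.seed(77)
  rate <- vapply(c(0, 1, 2.5), function(eff) {
    mean(replicate(150, {
      X <- matrix(rnorm(11 * 5), 11, 5)
      X[8:11, 1] <- X[8:11, 1] + eff
      pprnet:::hotelling_core(X, 1:7, 8:11)$p < 0.05
    }))
  }, 0)
  expect_true(all(diff(rate) >= 0))
  expect_gt(rate[3], rate[1])
})

test_that("regulatee_union matches a brute-force edge-list scan", {
  n1 <- toy_network("s1", data.frame(parent_tf = c("T1", "T1", "T2"),
                                     child_gene = c("A", "B", "C")))
  n2 <- toy_network("s2", data.frame(parent_tf = c("T1", "T3"),
                                     child_gene = c("B", "C")))
  nets <- list(n1, n2)
  expect_identical(regulatee_union("T1", nets), c("A", "B"))
  expect_identical(regulatee_union("T1", list(n1, toy_network("s3",
    data.frame(parent_tf = "T1", child_gene = "C")))), c("A", "B", "C"))
  expect_identical(regulatee_union("TX", nets), character(0))
  # oracle on the simulated networks
  pipe <- small_pipeline()
  tf <- pipe$ppr$tfs[1]
  want <- sort(unique(unlist(lapply(pipe$nets, function(n)
    n$edges$child_gene[n$edges$parent_tf == tf]))))
  expect_identical(regulatee_union(tf, pipe$nets), want)
})

test_that("a TF with no regulatees is reported as skipped with p = 1", {
  pipe <- small_pipeline()
  asg <- make_assignment(4, 3)
  names(asg$labels) <- colnames(pipe$ppr$z)
  r <- regulatee_hotelling("NOT_A_TF", pipe$ppr, asg, pipe$nets)
  expect_equal(r$p, 1)
  expect_equal(r$k, 0L)
})

test_that("rank_cluster_tfs ranks by delta, gates by p and q", {
  sim <- default_sim()
  pipe <- default_pipeline()
  sel <- select_variable_tfs(pipe$ppr, sim$expression)
  asg <- cluster_samples(pipe$ppr$z[sel, ], k = 2)
  rk <- rank_cluster_tfs(pipe$ppr, asg, pipe$nets_w)
  expect_true(!is.unsorted(rev(rk$delta_mean_z)))
  # BH q-values are monotone in p-rank
  o <- order(rk$p)
  expect_true(!is.unsorted(cummax(rk$q[o])))
  expect_true(all(rk$q >= 0 & rk$q <= 1))
  # selected implies shortlisted implies p < alpha
  expect_true(all(rk$p[rk$shortlisted] < 0.05))
  expect_true(all(rk$shortlisted[rk$selected]))
  # planted drivers are recovered
  drv <- unlist(sim$ground_truth$true_drivers)
  expect_true(all(drv %in% attr(rk, "selected")))
  # drivers rank high by delta; their regulatees can outrank them (the
  # generator amplifies regulon shifts by beta > 1), so the claim is
  # relative to the non-driver distribution, not a fixed decile
  expect_gt(median(rk$delta_mean_z[rk$tf %in% drv]),
            median(rk$delta_mean_z[!rk$tf %in% drv]))
})

test_that("DEG calling uses strict thresholds and a pooled t-test", {
  asg <- make_assignment(3, 3)
  samples <- names(asg$labels)
  # gene 'fold2' sits exactly at fold 2 (strict > excludes it);
  # 'up4' is a clean 4-fold change; 'flat' is identical
  expr <- rbind(fold2 = c(3.99, 3.99, 3.99, 1.99, 1.99, 1.99),
                up4 = c(40, 41, 39, 10, 10.2, 9.8),
                flat = c(5, 6, 7, 5, 6, 7))
  expr <- expr + 0 # keep numeric
  colnames(expr) <- samples
  expr["fold2", 1:3] <- 2 * expr["fold2", 4:6] + 0.01 # exact fold 2 with pseudocount
  degs <- compute_degs(expr, asg)
  expect_equal(degs$fold[degs$gene_id == "fold2"], 2, tolerance = 1e-12)
  expect_false(degs$deg[degs$gene_id == "fold2"])
  expect_true(degs$deg[degs$gene_id == "up4"])
  expect_false(degs$deg[degs$gene_id == "flat"])
  # t-test oracle
  tt <- t.test(log2(expr["up4", 1:3] + 1), log2(expr["up4", 4:6] + 1),
               var.equal = TRUE)
  expect_equal(degs$p[degs$gene_id == "up4"], tt$p.value, tolerance = 1e-12)
})

test_that("a planted strong fold change on simulated data is flagged", {
  sim <- default_sim()
  pipe <- default_pipeline()
  truth <- sim$ground_truth$true_clusters
  labels <- setNames(ifelse(truth == 1, "CL1", "CL2"), names(truth))
  asg <- structure(list(labels = labels, k = 2), class = "ClusterAssignment")
  degs <- compute_degs(sim$expression, asg)
  expect_gt(sum(degs$deg), 50) # the planted world has many true DEGs
  # all called DEGs really exceed 2-fold with p < 0.05
  expect_true(all(degs$fold[degs$deg] > 2 | degs$fold[degs$deg] < 0.5))
  expect_true(all(degs$p[degs$deg] < 0.05))
})

test_that("regulated_fraction reproduces the printed-count arithmetic", {
  deg_ids <- sprintf("D%03d", 1:589)
  net <- toy_network("s1", data.frame(parent_tf = "TF_X",
                                      child_gene = deg_ids[1:434]))
  rf <- regulated_fraction("TF_X", deg_ids, list(net))
  expect_equal(rf$n_regulated, 434L)
  expect_equal(rf$n_deg, 589L)
  expect_equal(rf$fraction, 434 / 589, tolerance = 1e-12)
  expect_equal(round(100 * rf$fraction), 74)

  none <- regulated_fraction("TF_ABSENT", deg_ids, list(net))
  expect_equal(none$fraction, 0)
  full <- regulated_fraction("TF_X", deg_ids[1:434], list(net))
  expect_equal(full$fraction, 1)
  expect_error(regulated_fraction("TF_X", character(0), list(net)), "no DEGs")
})

test_that("TF-TF subnetwork thresholds are strict", {
  # CL1 has 4 networks; the edge T1->T2 is present in 3/4 (= 0.75, excluded)
  # and T1->T3 in 4/4 with weight ratio 2 (included); T1->T4 has ratio
  # exactly 1.5 (excluded)
  mk <- function(id, edges) toy_network(id, edges)
  e_full <- function(w3, w4) data.frame(
    parent_tf = c("T1", "T1", "T1"), child_gene = c("T2", "T3", "T4"),
    weight = c(1, w3, w4))
  nets <- list(
    mk("a", e_full(2, 1.5)), mk("b", e_full(2, 1.5)),
    mk("c", e_full(2, 1.5)),
    mk("d", data.frame(parent_tf = c("T1", "T1"),
                       child_gene = c("T3", "T4"), weight = c(2, 1.5))),
    # CL2: edges present with weight 1
    mk("e", data.frame(parent_tf = c("T1", "T1", "T1"),
                       child_gene = c("T2", "T3", "T4"), weight = 1)),
    mk("f", data.frame(parent_tf = c("T1", "T1", "T1"),
                       child_gene = c("T2", "T3", "T4"), weight = 1)))
  labels <- setNames(c(rep("CL1", 4), rep("CL2", 2)),
                     c("a", "b", "c", "d", "e", "f"))
  asg <- structure(list(labels = labels, k = 2), class = "ClusterAssignment")
  sn <- tf_tf_subnetwork(nets, asg, "CL1", tfs = c("T1", "T2", "T3", "T4"))
  expect_false("T2" %in% sn$child_tf) # presence exactly 0.75
  expect_true("T3" %in% sn$child_tf)  # presence 1, ratio 2
  expect_false("T4" %in% sn$child_tf) # ratio exactly 1.5
  expect_equal(sn$presence[sn$child_tf == "T3"], 1)
  expect_equal(sn$weight_ratio[sn$child_tf == "T3"], 2, tolerance = 1e-9)
  expect_named(attr(sn, "out_degree"))
})

test_that("hypergeometric enrichment matches exact combinatorics", {
  # universe 20, one set of 5, query of 5 fully inside the set
  universe <- sprintf("g%02d", 1:20)
  coll <- list(hit = universe[1:5], other = universe[6:15])
  enr <- hypergeom_enrichment(universe[1:5], coll, universe)
  expect_equal(enr$p[enr$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  # query = universe: every set has p = 1
  enr2 <- hypergeom_enrichment(universe, coll, universe)
  expect_true(all(enr2$p == 1))
  expect_error(hypergeom_enrichment(c("nope"), coll, universe), "outside")
})

test_that("hypergeometric p equals brute-force enumeration (universe <= 30)", {
  set.seed(13)
  universe <- sprintf("u%02d", 1:24)
  gene_set <- sample(universe, 9)
  query <- sample(universe, 7)
  got <- hypergeom_enrichment(query, list(s = gene_set), universe)$p
  # enumerate all possible overlap counts of a random query of equal size
  ov <- length(intersect(query, gene_set))
  K <- length(gene_set); n <- length(universe); q <- length(query)
  want <- sum(vapply(ov:min(K, q), function(k)
    choose(K, k) * choose(n - K, q - k), 0)) / choose(n, q)
  expect_equal(got, want, tolerance = 1e-12)
})
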