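test_that("rare hosts are filtered and emptied taxa reported", {
  hosts <- list(G1 = c("X", "F1"), G2 = "F1", G3 = "X2")
  out <- filter_hosts(hosts, min_users = 2)
  expect_equal(out$dropped_hosts, c("X", "X2"))
  expect_equal(out$emptied_taxa, "G3")
  expect_equal(out$hosts$G1, "F1")
  # min_users = 1 is the identity
  expect_identical(filter_hosts(hosts, 1)$hosts, hosts)
})

test_that("breadth cap drops (or optionally truncates) polyphages", {
  hosts <- list(A = paste0("F", 1:6), B = c("F1", "F2"))
  out <- apply_breadth_cap(hosts, 5)
  expect_equal(out$dropped_taxa, "A")
  expect_equal(names(out$hosts), "B")
  # everything under the cap: identity
  expect_identical(apply_breadth_cap(hosts, 6)$hosts, hosts)
  # truncation keeps the taxon with its most widely used hosts
  tr <- apply_breadth_cap(list(A = paste0("F", 1:6), B = c("F1", "F2"),
                               C = c("F1", "F3")), 2, truncate = TRUE)
  expect_equal(tr$truncated_taxa, "A")
  expect_length(tr$hosts$A, 2)
  expect_true("F1" %in% tr$hosts$A)
})

test_that("decomposition accepts the root when it already qualifies", {
  set.seed(2)
  tr <- ape::rphylo(40, 1, 0)
  hosts <- setNames(lapply(1:40, function(i) sample(paste0("F", 1:6), 2)),
                    tr$tip.label)
  dec <- decompose_tree(tr, hosts, min_tips = 10, max_states = 1600,
                        max_breadth = 5)
  expect_length(dec$subtrees, 1)
  expect_equal(dec$manifest$n_tips, 40L)
  expect_length(dec$excluded_tips, 0)
  # 6 hosts under cap 5 -> 62 states, well under the cap
  expect_equal(dec$manifest$n_states, 62L)
})

test_that("decomposition splits exactly where the state cap forces it", {
  # two 20-tip clades, each using 8 local host families, joined at a root
  # whose pooled 16 families blow past a 300-state cap
  left <- ape::rphylo(20, 1, 0)
  right <- ape::rphylo(20, 1, 0)
  left$tip.label <- paste0("L", 1:20)
  right$tip.label <- paste0("R", 1:20)
  tr <- ape::bind.tree(ape::read.tree(text = "(A:1,B:1);"), left, where = 1)
  tr <- ape::bind.tree(tr, right, where = which(tr$tip.label == "B"))
  set.seed(4)
  hosts <- c(
    setNames(lapply(1:20, function(i) sample(paste0("LF", 1:8), 2)), paste0("L", 1:20)),
    setNames(lapply(1:20, function(i) sample(paste0("RF", 1:8), 2)), paste0("R", 1:20))
  )
  dec <- decompose_tree(tr, hosts, min_tips = 10, max_states = 300,
                        max_breadth = 5)
  # root: 16 hosts -> sum(choose(16,1:5)) = 6885 >= 300; children: 8 hosts
  # -> 218 < 300: exactly two subtrees
  expect_length(dec$subtrees, 2)
  expect_equal(sort(dec$manifest$n_hosts), c(8L, 8L))
  expect_true(all(dec$manifest$n_states < 300))

  # maximality by brute force: no ancestor of an accepted clade qualifies
  desc <- hostshift:::descendant_tips(tr)
  qualifies <- function(node) {
    tips <- tr$tip.label[desc[[node]]]
    hs <- unique(unlist(hosts[intersect(tips, names(hosts))]))
    length(tips) >= 10 && state_count(length(hs), 5) < 300
  }
  for (root in dec$manifest$root) {
    anc <- tr$edge[tr$edge[, 2] == root, 1]
    while (length(anc) == 1) {
      expect_false(qualifies(anc))
      anc <- tr$edge[tr$edge[, 2] == anc, 1]
    }
  }
})

test_that("decomposition is disjoint, deterministic, and reports exclusions", {
  set.seed(9)
  tr <- ape::rphylo(64, 1, 0)
  hosts <- setNames(lapply(1:64, function(i)
    sample(paste0("F", 1:20), sample(1:3, 1))), tr$tip.label)
  dec <- decompose_tree(tr, hosts, min_tips = 8, max_states = 150,
                        max_breadth = 5)
  # disjoint tip sets
  tip_sets <- lapply(dec$subtrees, function(s) s$tip.label)
  expect_equal(anyDuplicated(unlist(tip_sets)), 0)
  # every accepted clade satisfies both constraints post hoc
  expect_true(all(dec$manifest$n_tips >= 8))
  expect_true(all(dec$manifest$n_states < 150))
  # determinism
  dec2 <- decompose_tree(tr, hosts, min_tips = 8, max_states = 150,
                         max_breadth = 5)
  expect_identical(dec$manifest, dec2$manifest)
  # covered tips are either inside a subtree or listed excluded
  covered <- names(hosts)
  inside <- unlist(tip_sets)
  expect_setequal(c(intersect(covered, inside), dec$excluded_tips), covered)

  dir <- withr::local_tempdir()
  write_decomposition(dec, dir)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
})

test_that("no qualifying clade is an error", {
  tr <- ape::rphylo(6, 1, 0)
  hosts <- setNames(rep(list("F1"), 6), tr$tip.label)
  dec <- decompose_tree(tr, hosts, min_tips = 10, max_states = 1600)
  expect_length(dec$subtrees, 0) # reported empty; pipeline turns it into an error
})
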