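toy_recon <- function(tree, map_states, probs = NULL) {
  # minimal dec_recon stand-in: MAP labels per internal node
  n_tip <- ape::Ntip(tree)
  nodes <- (n_tip + 1):(n_tip + tree$Nnode)
  probs <- probs %||% rep(1, length(nodes))
  structure(list(
    map = tibble::tibble(node = nodes, state = map_states,
                         state_idx = NA_integer_, prob = probs),
    node_probs = NULL, labels = unique(map_states)
  ), class = "dec_recon")
}

test_that("event classification follows set differences of MAP states", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # nodes 5 (root), 6, 7
  rec <- toy_recon(tr, c("a", "a+b", "b"), probs = c(0.9, 0.8, 0.7))
  ev <- classify_events(rec, tr)
  ev6 <- ev[ev$node == 6, ]
  ev7 <- ev[ev$node == 7, ]
  expect_equal(ev6$class, "gain")
  expect_equal(ev6$gained, "b")
  expect_equal(ev6$lost, "")
  expect_equal(ev7$class, "complex") # {a} -> {b}: simultaneous gain and loss
  expect_equal(ev7$gained, "b")
  expect_equal(ev7$lost, "a")
  # product weight: node MAP x parent MAP
  expect_equal(ev6$weight, 0.8 * 0.9)
  expect_equal(classify_events(rec, tr, weight = "node")$weight[1], 0.8)
  # loss case
  rec2 <- toy_recon(tr, c("a+b", "a", "a+b"))
  ev2 <- classify_events(rec2, tr)
  expect_equal(ev2$class[ev2$node == 6], "loss")
  expect_equal(ev2$lost[ev2$node == 6], "b")
  expect_equal(ev2$class[ev2$node == 7], "none")
})

test_that("waiting-time contrasts are mean child-branch differences", {
  tr <- ape::read.tree(text = "(((A:1,B:3):1,(C:2,D:2):1):1,E:4);")
  # node 8 = (A,B): child branches 1,3 (mean 2); sister node 9 = (C,D): 2,2
  wt <- waiting_time_contrast(tr, 8)
  expect_equal(wt$value, 0)
  wt2 <- waiting_time_contrast(tr, 9)
  expect_equal(wt2$value, 0) # antisymmetric at the same pair
  # tip-sister case is skipped
  expect_null(waiting_time_contrast(tr, 7)) # sister is tip E
  tr2 <- ape::read.tree(text = "(((A:0.5,B:1.5):1,(C:2,D:4):1):1,E:4);")
  expect_equal(waiting_time_contrast(tr2, 8)$value, -2)
  expect_equal(waiting_time_contrast(tr2, 9)$value, 2)
})

test_that("diversity contrasts implement the exclusive and inclusive counting rules", {
  tr <- ape::read.tree(text = "(((G1:1,G2:1):1,(G3:1,G4:1):1):1,E:3);")
  rich <- c(G1 = 5, G2 = 3, G3 = 4, G4 = 7, E = 1)
  hosts <- list(G1 = "h", G2 = "x", G3 = "h", G4 = "x", E = "x")
  # gain of h at node 8 (clade G1,G2), sister node 9 (G3,G4):
  # focal users of h: G1 (5); sister non-users: G4 (7) -> 5 - 7 = -2
  expect_equal(diversity_contrast(tr, 8, 9, "exclusive", "gain", "h",
                                  hosts, rich), -2)
  # loss of h, same table: focal non-users G2 (3) - sister users G3 (4) = -1
  expect_equal(diversity_contrast(tr, 8, 9, "exclusive", "loss", "h",
                                  hosts, rich), -1)
  # inclusive ignores host use: (5+3) - (4+7) = -3
  expect_equal(diversity_contrast(tr, 8, 9, "inclusive", "gain", "h",
                                  hosts, rich), -3)
  # antisymmetry
  expect_equal(diversity_contrast(tr, 9, 8, "inclusive", richness = rich), 3)
  # empty-side sums: no focal tip uses h after a gain
  hosts0 <- list(G1 = "x", G2 = "x", G3 = "h", G4 = "x", E = "x")
  expect_equal(diversity_contrast(tr, 8, 9, "exclusive", "gain", "h",
                                  hosts0, rich), 0 - 7)
  # 'none' events count everything on both sides
  expect_equal(diversity_contrast(tr, 8, 9, "exclusive", "none",
                                  character(0), hosts, rich), -3)
  # missing richness entries are an error
  expect_error(diversity_contrast(tr, 8, 9, "inclusive",
                                  richness = c(G1 = 1)), "richness")
})

test_that("contrasts vanish on a fully symmetric tree with equal richness", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  rec <- toy_recon(tr, rep("a", tr$Nnode))
  ev <- classify_events(rec, tr)
  ctr <- suppressMessages(
    sister_contrasts(ev, tr, richness = setNames(rep(2, 8), tr$tip.label),
                     hosts = setNames(rep(list("a"), 8), tr$tip.label)))
  expect_true(all(ctr$value == 0))
})

test_that("swapping focal and sister negates every contrast", {
  set.seed(31)
  tr <- ape::rphylo(12, 1, 0)
  rich <- setNames(sample(1:20, 12, replace = TRUE), tr$tip.label)
  desc <- hostshift:::descendant_tips(tr)
  for (v in 14:19) {
    s <- hostshift:::sister_node(tr, v)
    if (is.na(s)) next
    a <- diversity_contrast(tr, v, s, "inclusive", richness = rich)
    b <- diversity_contrast(tr, s, v, "inclusive", richness = rich)
    expect_equal(a, -b)
  }
})

test_that("pruned-tree nodes map to complete-tree MRCAs with absorption flags", {
  full <- ape::read.tree(text = "(((A:1,X:1):1,B:2):1,C:3);")
  pruned <- ape::drop.tip(full, "X")
  # clade {A,B} in the pruned tree maps to MRCA(A,B) in the full tree,
  # which also subtends X
  m <- map_clade_node(pruned, full, 5) # root of pruned {A,B} clade
  expect_equal(sort(full$tip.label[hostshift:::descendant_tips(full)[[m$node]]]),
               c("A", "B", "X"))
  expect_equal(m$absorbed, "X")
  # identity map when the trees agree
  m2 <- map_clade_node(full, full, 6)
  expect_equal(m2$node, 6)
  expect_length(m2$absorbed, 0)
  # root maps to root
  expect_equal(map_clade_node(pruned, full, 4)$node, 5)
})

test_that("classification recovers true labels at high-confidence nodes", {
  # mild rates so that confident nodes exist; pooled across replicates
  agree <- 0L; n_conf <- 0L
  for (r in 1:3) {
    tr <- sim_bd_tree(80, birth = 0.1, seed = 600 + r)
    tr$edge.length <- tr$edge.length * 50 / max(ape::node.depth.edgelength(tr))
    sp <- host_state_space(paste0("H", 1:4), 3)
    h <- sim_host_history(tr, sp, 0.01, 0.01, seed = 700 + r)
    rec <- dec_ancestral_states(tr, h$tip_states, sp, 0.01, 0.01)
    ev <- classify_events(rec, tr)
    m <- dplyr::inner_join(ev, h$events, by = "node",
                           suffix = c("", ".true"))
    conf <- m$weight > 0.95
    agree <- agree + sum(m$class[conf] == m$class.true[conf])
    n_conf <- n_conf + sum(conf)
  }
  expect_gt(n_conf, 30)
  expect_gte(agree / n_conf, 0.9)
})
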