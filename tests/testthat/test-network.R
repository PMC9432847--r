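test_that("validation accepts a minimal tree and reports specific violations", {
  net <- make_toy_network("single")
  expect_identical(validate_network(net), character(0))

  ## duplicated edge creates a cycle (segments != nodes - 1)
  bad <- net
  extra <- bad$segments[1, ]; extra$id <- "s2"
  bad$segments <- rbind(bad$segments, extra)
  expect_true(any(grepl("acyclic", validate_network(bad))))

  bad2 <- net
  bad2$segments$diameter_um[1] <- 0
  expect_true(any(grepl("diameter > 0", validate_network(bad2))))

  bad3 <- make_toy_network("y_split")
  bad3$nodes$x[2] <- NaN
  expect_true(any(grepl("not finite", validate_network(bad3))))
})

test_that("mouse-to-human scaling multiplies diameters, lengths, coordinates", {
  net <- make_toy_network("two_level")
  sc <- scale_network(net, 3.6, 5.9)
  expect_equal(sc$segments$diameter_um, net$segments$diameter_um * 3.6)
  expect_equal(sc$segments$length_cm, net$segments$length_cm * 5.9)
  expect_equal(sc$nodes$x, net$nodes$x * 5.9)
  ## 10 um at factor 3.6 -> 36 um; 0.1 cm at 5.9 -> 0.59 cm
  one <- net; one$segments$diameter_um[1] <- 10; one$segments$length_cm[1] <- 0.1
  sone <- scale_network(one, 3.6, 5.9)
  expect_equal(sone$segments$diameter_um[1], 36)
  expect_equal(sone$segments$length_cm[1], 0.59)
  ## identity and invertibility
  expect_equal(scale_network(net, 1, 1), net)
  back <- scale_network(sc, 1 / 3.6, 1 / 5.9)
  expect_equal(back$segments$diameter_um, net$segments$diameter_um,
               tolerance = 1e-12)
  expect_equal(back$nodes$y, net$nodes$y, tolerance = 1e-12)
  expect_error(scale_network(net, -1, 1), "positive")
})

test_that("synthetic generator is seeded, counts branches, and obeys Murray's law", {
  a <- generate_synthetic_tree(seed = 11)
  b <- generate_synthetic_tree(seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_synthetic_tree(seed = 12)))

  ## level-1 tree: main branches are the terminals
  t1 <- generate_synthetic_tree(n_main_branches = 4, bifurcation_levels = 1,
                                seed = 1)
  expect_equal(nrow(t1$segments), 4)
  expect_equal(sum(t1$nodes$kind == "terminal"), 4)

  ## symmetric noiseless split: daughters = root / 2^(1/3)
  t2 <- generate_synthetic_tree(n_main_branches = 1, bifurcation_levels = 2,
                                murray_exponent = 3, root_diameter_um = 36,
                                terminal_diameter_um = NULL, jitter = 0,
                                seed = 1)
  d <- sort(unique(t2$segments$diameter_um), decreasing = TRUE)
  expect_equal(d[1], 36)
  expect_equal(d[2], 36 / 2^(1 / 3), tolerance = 1e-12)

  ## the Murray relation D_p^k = sum D_d^k holds at every bifurcation even
  ## with jitter (the split fraction is drawn, then mapped through Murray)
  t3 <- classify_segments(generate_synthetic_tree(
    bifurcation_levels = 4, jitter = 0.4, terminal_diameter_um = NULL,
    murray_exponent = 2.7, seed = 99))
  sg <- t3$segments
  kids <- split(seq_len(nrow(sg)), sg$from)
  for (nd in names(kids)) {
    if (length(kids[[nd]]) != 2) next
    parent <- which(sg$to == nd)
    if (length(parent) == 0) next
    expect_equal(sg$diameter_um[parent]^2.7,
                 sum(sg$diameter_um[kids[[nd]]]^2.7), tolerance = 1e-9)
  }

  ## structural invariants
  for (net in list(a, t1, t3)) {
    expect_length(validate_network(net), 0)
    expect_equal(nrow(net$segments), nrow(net$nodes) - 1)
  }
  ## uniform terminal diameters when requested
  term <- a$segments$diameter_um[a$segments$to %in%
                                   a$nodes$id[a$nodes$kind == "terminal"]]
  expect_true(all(term == term[1]))
  expect_error(generate_synthetic_tree(), "seed")
  expect_error(generate_synthetic_tree(seed = 1, jitter = 2), "jitter")
})

test_that("segment classification labels SA/LA and enumerates pathways", {
  ## degenerate single-segment pathway: the terminal is its own main branch
  s1 <- classify_segments(make_toy_network("single"))
  expect_equal(s1$segments$class, "SA")
  expect_equal(s1$pathways$D_LA_um, s1$pathways$D_SA_um)

  y <- classify_segments(make_toy_network("y_split"))
  expect_equal(y$segments$class[y$segments$id == "s1"], "LA")
  expect_equal(sort(y$segments$class), c("LA", "SA", "SA"))
  expect_equal(nrow(y$pathways), 2)
  expect_true(all(y$pathways$D_LA_um == 50))
  expect_equal(sort(y$pathways$terminal_node), c("n2", "n3"))

  f4 <- classify_segments(make_toy_network("four_branch"))
  expect_equal(nrow(f4$pathways), 4)
  expect_equal(sum(f4$segments$class == "SA"), 4)
  expect_equal(sum(f4$segments$class == "LA"), 0)

  no_term <- make_toy_network("single")
  no_term$nodes$kind[2] <- "junction"
  no_term$segments <- no_term$segments  # still a dangling junction
  expect_error(classify_segments(no_term), "terminal")
})

test_that("network CSV and JSON round-trips are bit-exact", {
  net <- classify_segments(generate_synthetic_tree(bifurcation_levels = 3,
                                                   jitter = 0.3, seed = 5))
  td <- withr::local_tempdir()
  nf <- file.path(td, "nodes.csv"); sf <- file.path(td, "segments.csv")
  write_network_csv(net, nf, sf)
  back <- read_network_csv(nf, sf)
  expect_identical(back$nodes$x, net$nodes$x)
  expect_identical(back$segments$diameter_um, net$segments$diameter_um)
  expect_identical(back$segments$length_cm, net$segments$length_cm)

  jf <- file.path(td, "net.json")
  write_network_json(net, jf)
  bj <- read_network_json(jf)
  expect_identical(bj$nodes$x, net$nodes$x)
  expect_identical(bj$segments$length_cm, net$segments$length_cm)
  expect_identical(as.numeric(bj$inlet_pressure), as.numeric(net$inlet_pressure))
})
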