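test_that("a minimal two-species network file loads and validates", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "species:",
    "  - {name: A, module: input}",
    "  - {name: B, module: other}",
    "edges:",
    "  - {target: B, activators: [A], sign: production}",
    "inputs: [A]"), f)
  net <- load_network(f)
  expect_s3_class(net, "ecm_network")
  expect_equal(nrow(net$species), 2L)
  expect_length(net$edges, 1L)
  expect_equal(net$inputs, "A")
  expect_equal(as.numeric(net$rates), as.numeric(rate_constants()))
})

test_that("schema violations are rejected with the offending name", {
  base <- c("species:",
            "  - {name: A, module: input}",
            "inputs: [A]")
  f1 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(base[1:2], "  - {name: A, module: other}", base[3],
               "edges: []"), f1)
  expect_error(load_network(f1), "duplicate species name: A")

  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(base[1:2], base[3],
               "edges:",
               "  - {target: Zz, activators: [A], sign: production}"), f2)
  expect_error(load_network(f2), "Zz")

  f3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(base[1:2], base[3],
               "edges:",
               "  - {target: A, activators: [A], sign: production, rate: -1}"),
             f3)
  expect_error(load_network(f3), "non-positive rate")

  expect_error(
    network_spec(data.frame(name = "A", module = "other"),
                 edges = list(list(target = "A", activators = character(),
                                   sign = "production"))),
    "names no activators")
})

test_that("the reference network reproduces the published architecture", {
  net <- build_reference_network()
  cen <- network_census(net)
  expect_identical(cen$n_species, 132L)
  expect_gte(cen$n_edges, 200L)
  expect_identical(unname(cen$by_module[c(
    "input", "receptor", "second_messenger", "kinase_phosphatase", "mapk",
    "transcription_factor", "mechanotransduction")]),
    c(10L, 10L, 8L, 15L, 12L, 8L, 18L))
  expect_gte(cen$by_module[["ecm_precursor"]], 17L)
  expect_setequal(net$inputs, c("TGFB", "AngII", "IL6", "IL1", "TNFa",
                                "NE", "PDGF", "ET1", "NP", "E2"))
  expect_identical(net$feedback_fields$name,
                   c("TGFBfb", "AngIIfb", "IL6fb", "ET1fb"))
  expect_gte(nrow(net$ecm_fields), 17L)
  expect_true(all(c("proCI", "proCIII", "proMMP1", "proMMP2", "proMMP3",
                    "proMMP8", "proMMP9", "proMMP12", "proMMP14", "TIMP1",
                    "TIMP2", "CTGF", "periostin", "fibronectin",
                    "tenascinC", "thrombospondin4", "osteopontin") %in%
                    net$ecm_fields$name))
})

test_that("the packaged YAML file and the in-code builder agree", {
  from_file <- load_network(reference_network_path())
  built <- build_reference_network()
  expect_identical(from_file$species, built$species)
  expect_identical(from_file$inputs, built$inputs)
  expect_identical(from_file$feedback_fields, built$feedback_fields)
  expect_identical(from_file$ecm_fields, built$ecm_fields)
  expect_length(from_file$edges, length(built$edges))
  # identical dynamics on a random state
  set.seed(42)
  x <- setNames(runif(132), built$species$name)
  iext <- setNames(runif(10), built$inputs)
  fb <- setNames(runif(4), built$feedback_fields$name)
  expect_equal(cell_derivatives(x, iext, fb, from_file),
               cell_derivatives(x, iext, fb, built), tolerance = 1e-15)
})

test_that("every ECM precursor is reachable from the inputs", {
  net <- build_reference_network()
  reach <- reachable_from(net, net$inputs)
  expect_true(all(net$ecm_fields$precursor %in% reach))
  # and specifically TGF-beta reaches the collagen I precursor
  expect_true("proCI" %in% reachable_from(net, "TGFB"))
})

test_that("BFS reachability agrees with igraph on the reference network", {
  net <- build_reference_network()
  el <- do.call(rbind, lapply(net$edges, function(e) {
    if (e$sign != "production") return(NULL)
    cbind(e$activators, e$target)
  }))
  g <- igraph::graph_from_edgelist(el, directed = TRUE)
  ig_reach <- names(igraph::subcomponent(g, "TGFB", mode = "out"))
  expect_setequal(intersect(reachable_from(net, "TGFB"), igraph::V(g)$name),
                  ig_reach)
})
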