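test_that("a minimal activation relation parses into one signed link", {
  doc <- kgml_build(kgml_scenario(
    genes = list(e1 = "hsa:1", e2 = "hsa:2"),
    relations = data.frame(source = "e1", target = "e2",
                           subtype = "activation")))
  pm <- parse_kgml(doc)
  expect_s3_class(pm, "pathway_model")
  expect_equal(nrow(pm$entries), 2L)
  expect_equal(nrow(pm$links), 1L)
  expect_equal(pm$links$sign, "activating")
  expect_equal(pm$links$source, "e1")
  expect_equal(pm$links$target, "e2")
})

test_that("inhibition and unannotated subtypes map to the right signs", {
  doc <- kgml_build(kgml_scenario(
    genes = list(e1 = "hsa:1", e2 = "hsa:2", e3 = "hsa:3"),
    relations = data.frame(source = c("e1", "e2"), target = c("e2", "e3"),
                           subtype = c("inhibition", "phosphorylation"))))
  pm <- parse_kgml(doc)
  expect_equal(pm$links$sign, c("inhibiting", "unknown"))
})

test_that("a compound-subtype relation decomposes through the compound", {
  doc <- kgml_build(kgml_scenario(
    genes = list(e1 = "hsa:1", e2 = "hsa:2"),
    compounds = list(c1 = "cpd:C00001"),
    relations = data.frame(source = "e1", target = "e2",
                           subtype = "compound", compound = "c1")))
  pm <- parse_kgml(doc)
  expect_equal(nrow(pm$links), 2L)
  expect_equal(paste(pm$links$source, pm$links$target),
               c("e1 c1", "c1 e2"))
})

test_that("a reversible reaction emits all four substrate/enzyme/product links", {
  doc <- kgml_build(kgml_scenario(
    genes = list(eg = "hsa:9"),
    compounds = list(cs = "cpd:C00010", cp = "cpd:C00020"),
    reactions = data.frame(id = "rn1", name = "rn:R00001",
                           substrate = "cs", product = "cp",
                           enzyme = "eg", reversible = TRUE)))
  pm <- parse_kgml(doc)
  got <- sort(paste(pm$links$source, pm$links$target))
  expect_equal(got, sort(c("cs eg", "eg cp", "cp eg", "eg cs")))

  irr <- kgml_build(kgml_scenario(
    genes = list(eg = "hsa:9"),
    compounds = list(cs = "cpd:C00010", cp = "cpd:C00020"),
    reactions = data.frame(id = "rn1", name = "rn:R00001",
                           substrate = "cs", product = "cp",
                           enzyme = "eg", reversible = FALSE)))
  expect_equal(nrow(parse_kgml(irr)$links), 2L)
})

test_that("binding/association relations are emitted in both directions", {
  doc <- kgml_build(kgml_scenario(
    genes = list(e1 = "hsa:1", e2 = "hsa:2"),
    relations = data.frame(source = "e1", target = "e2",
                           subtype = "binding/association")))
  pm <- parse_kgml(doc)
  expect_setequal(paste(pm$links$source, pm$links$target),
                  c("e1 e2", "e2 e1"))
})

test_that("relations to missing entries are skipped with a warning", {
  doc <- kgml_build(kgml_scenario(
    genes = list(e1 = "hsa:1"),
    relations = data.frame(source = "e1", target = "e99",
                           subtype = "activation")))
  expect_warning(pm <- parse_kgml(doc), "missing entry")
  expect_equal(nrow(pm$links), 0L)
})

test_that("malformed XML and unknown entry types are reported", {
  expect_error(parse_kgml("<pathway><entry id='1'"), class = "error")
  expect_error(parse_kgml("<notkgml/>"), "root element")
  doc <- paste0('<pathway name="p" title="t">',
                '<entry id="1" name="x:1" type="widget"/></pathway>')
  expect_warning(pm <- parse_kgml(doc), "widget")
  expect_equal(pm$entries$kind, "other")
})

test_that("group entries flatten to their members in the hetero graph", {
  doc <- kgml_build(kgml_scenario(
    genes = list(ea = "A", eb = "B", ec = "C"),
    groups = list(grp = c("ea", "eb")),
    relations = data.frame(source = "grp", target = "ec",
                           subtype = "activation")))
  h <- build_hetero_graph(parse_kgml(doc))
  expect_setequal(h$nodes$name, c("A", "B", "C"))
  expect_setequal(paste(h$edges$from, h$edges$to), c("A C", "B C"))
})

test_that("multi-identifier entries expand with inherited links", {
  doc <- kgml_build(kgml_scenario(
    genes = list(eg = c("g1", "g2")),
    compounds = list(cx = "X"),
    relations = data.frame(source = "cx", target = "eg",
                           subtype = "activation")))
  h <- build_hetero_graph(parse_kgml(doc))
  expect_setequal(paste(h$edges$from, h$edges$to), c("X g1", "X g2"))
  expect_equal(sort(h$nodes$kind), c("compound", "gene", "gene"))
})

test_that("an empty pathway yields an empty hetero graph", {
  pm <- parse_kgml('<pathway name="p" title="t"></pathway>')
  h <- build_hetero_graph(pm)
  expect_equal(nrow(h$nodes), 0L)
  expect_equal(nrow(h$edges), 0L)
})

test_that("ortholog entries are gene-kind only when the flag is set", {
  doc <- kgml_build(kgml_scenario(
    orthologs = list(ko1 = "ko:K00001"),
    genes = list(e1 = "hsa:1")))
  pm <- parse_kgml(doc)
  expect_true("ortholog" %in% pm$entries$kind)
  h_off <- build_hetero_graph(pm)
  h_on <- build_hetero_graph(pm, orthologs_as_genes = TRUE)
  expect_equal(h_off$nodes$kind[h_off$nodes$name == "ko:K00001"], "other")
  expect_equal(h_on$nodes$kind[h_on$nodes$name == "ko:K00001"], "gene")
})

test_that("duplicate edges merge and sign conflicts collapse to unknown", {
  doc <- kgml_build(kgml_scenario(
    genes = list(e1 = "A", e2 = "B"),
    relations = data.frame(source = c("e1", "e1"), target = c("e2", "e2"),
                           subtype = c("activation", "inhibition"))))
  h <- build_hetero_graph(parse_kgml(doc))
  expect_equal(nrow(h$edges), 1L)
  expect_equal(h$edges$sign, "unknown")
})

test_that("parsing is deterministic and fixtures round-trip their inventory", {
  for (seed in c(11L, 12L, 13L, 14L, 15L)) {
    sc <- random_kgml_scenario(seed, cyclic = (seed %% 2L == 0L))
    doc <- kgml_build(sc)
    pm1 <- suppressWarnings(parse_kgml(doc))
    pm2 <- suppressWarnings(parse_kgml(doc))
    expect_identical(pm1, pm2)
    intended <- attr(sc, "intended")
    expect_equal(nrow(pm1$links), intended$n_links)
    h <- build_hetero_graph(pm1)
    expect_identical(h$nodes$name[h$nodes$kind == "gene"],
                     intended$gene_names)
    expect_identical(sort(h$nodes$name[h$nodes$kind == "compound"],
                          method = "radix"),
                     intended$compound_names)
  }
})
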