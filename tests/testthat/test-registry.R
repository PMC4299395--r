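# Registry lifecycle: assignment, merge, split, relocation, versions,
# variants, synonyms, history, event-sourcing.

test_that("identifier assignment increments by exactly one, per chromosome", {
  reg <- registry_new()
  expect_equal(format_locus_id(create_gene(reg, 7)), "Vitvi07g00001")
  expect_equal(format_locus_id(create_gene(reg, 7)), "Vitvi07g00002")
  expect_equal(format_locus_id(create_gene(reg, 3)), "Vitvi03g00001")

  seeded <- registry_new(counters = c(rep(0L, 18), 12230L, 0L))  # chr 18
  expect_equal(format_locus_id(create_gene(seeded, 18)), "Vitvi18g12231")
})

test_that("a chromosome holds at most 99,999 numeric codes", {
  full <- registry_new(counters = c(rep(0L, 5), 99999L, rep(0L, 14)))
  expect_error(create_gene(full, 5), class = "registry_capacity_error")
  expect_equal(format_locus_id(create_gene(full, 6)), "Vitvi06g00001")
})

test_that("merging retires the discarded identifier and records it as synonym", {
  reg <- registry_new(counters = c(rep(0L, 18), 12229L, 0L))
  a <- create_gene(reg, 18)   # 12230
  b <- create_gene(reg, 18)   # 12231
  merge_genes(reg, a, b)

  surv <- get_record(reg, a)
  disc <- get_record(reg, b)
  expect_equal(disc$status, "retired")
  expect_equal(disc$successor, "Vitvi18g12230")
  expect_true("Vitvi18g12231" %in% surv$synonyms$name)
  expect_equal(surv$version, 2L)

  # the discarded code is never reissued
  expect_equal(format_locus_id(create_gene(reg, 18)), "Vitvi18g12232")
  # retired ids resolve through the successor link
  expect_equal(format_locus_id(resolve_id(reg, b)), "Vitvi18g12230")
})

test_that("degenerate merges are refused", {
  reg <- registry_new()
  a <- create_gene(reg, 1)
  b <- create_gene(reg, 2)
  c_ <- create_gene(reg, 1, object_type = "te")
  expect_error(merge_genes(reg, a, a), class = "registry_self_merge_error")
  expect_error(merge_genes(reg, a, b),
               class = "registry_cross_chromosome_error")
  expect_error(merge_genes(reg, a, c_), class = "registry_object_type_error")
  d <- create_gene(reg, 1)
  merge_genes(reg, a, d)
  expect_error(merge_genes(reg, a, d), class = "registry_retired_id_error")
})

test_that("splitting keeps the original id and issues fresh increasing codes", {
  reg <- registry_new(counters = c(rep(0L, 18), 12229L, 0L))
  orig <- create_gene(reg, 18)            # 12230
  create_gene(reg, 18)                    # 12231 occupies the counter
  new_ids <- split_gene(reg, orig, 1)
  expect_equal(format_locus_id(new_ids[[1]]), "Vitvi18g12232")
  rec <- get_record(reg, orig)
  expect_equal(rec$status, "active")
  expect_equal(rec$version, 2L)

  two <- split_gene(reg, orig, 2)
  codes <- vapply(two, function(x) x$numeric_code, integer(1))
  expect_equal(codes, c(12233L, 12234L))
  merge_genes(reg, orig, "Vitvi18g12231")
  expect_error(split_gene(reg, "Vitvi18g12231"),
               class = "registry_retired_id_error")
})

test_that("relocation from chromosome 00 issues the next code in series", {
  reg <- registry_new(counters = c(119L, rep(0L, 6), 1538L, rep(0L, 12)))
  old <- create_gene(reg, 0)              # Vitvi00g00120
  expect_equal(format_locus_id(old), "Vitvi00g00120")
  new_id <- relocate_gene(reg, old, 7)
  expect_equal(format_locus_id(new_id), "Vitvi07g01539")

  old_rec <- get_record(reg, old)
  expect_equal(old_rec$status, "retired")
  expect_equal(old_rec$successor, "Vitvi07g01539")
  expect_true("Vitvi00g00120" %in% get_record(reg, new_id)$synonyms$name)

  # the vacated chromosome-00 code is never reissued
  expect_equal(format_locus_id(create_gene(reg, 0)), "Vitvi00g00121")
  expect_error(relocate_gene(reg, new_id, 7),
               class = "registry_same_chromosome_error")
})

test_that("version bumps add exactly one and accumulate", {
  reg <- registry_new()
  id <- create_gene(reg, 4)
  expect_equal(get_record(reg, id)$version, 1L)
  expect_equal(bump_version(reg, id), 2L)
  bump_version(reg, id); bump_version(reg, id)
  expect_equal(get_record(reg, id)$version, 4L)
})

test_that("the Tempranillo allele/splice scenario allocates unique tokens", {
  reg <- registry_new()
  t_id <- create_gene(reg, 5, object_type = "t")
  forms <- list(a = c(1, 2, 3), b = c(1, 2, 4), c = c(1, 2, 3))
  with_prefix <- unlist(lapply(names(forms), function(al)
    vapply(forms[[al]], function(s)
      allocate_variant(reg, t_id, al, s, cultivar_prefix = "tp"),
      character(1))))
  expect_equal(with_prefix,
               c("tpa1", "tpa2", "tpa3", "tpb1", "tpb2", "tpb4",
                 "tpc1", "tpc2", "tpc3"))
  bare <- unlist(lapply(names(forms), function(al)
    vapply(forms[[al]], function(s) allocate_variant(reg, t_id, al, s),
           character(1))))
  expect_equal(bare, c("a1", "a2", "a3", "b1", "b2", "b4",
                       "c1", "c2", "c3"))

  expect_error(allocate_variant(reg, t_id, "a", 1),
               class = "registry_duplicate_variant_error")
  g_id <- create_gene(reg, 5, object_type = "g")
  expect_error(allocate_variant(reg, g_id, "a", 1),
               class = "registry_splice_error")
  # letter-only allele on a gene object is fine
  expect_equal(allocate_variant(reg, g_id, "a"), "a")
})

test_that("synonyms keep notes and refuse duplicates per (name, kind)", {
  reg <- registry_new()
  nced3 <- create_gene(reg, 19)
  rename_gene(reg, nced3, "NCED3")
  add_synonym(reg, nced3, "NCED1", kind = "symbol", note = "incorrect",
              note_text = "applied to this gene in earlier work")
  rec <- get_record(reg, nced3)
  expect_equal(rec$synonyms$note[rec$synonyms$name == "NCED1"], "incorrect")

  # an ambiguous name may sit on several genes, each carrying the note
  g1 <- create_gene(reg, 2); g2 <- create_gene(reg, 2)
  add_synonym(reg, g1, "CCD4b", note = "ambiguous")
  add_synonym(reg, g2, "CCD4b", note = "ambiguous")
  expect_equal(get_record(reg, g1)$synonyms$note, "ambiguous")
  expect_equal(get_record(reg, g2)$synonyms$note, "ambiguous")

  expect_error(add_synonym(reg, g1, "ccd4b", note = "ambiguous"),
               class = "registry_duplicate_synonym_error")
  # same name under a different kind is allowed
  add_synonym(reg, g1, "CCD4b", kind = "full_name")
})

test_that("history is ordered, complete, and survives retirement", {
  reg <- registry_new()
  a <- create_gene(reg, 9)
  bump_version(reg, a)
  b <- create_gene(reg, 9)
  merge_genes(reg, b, a)

  ha <- get_history(reg, a)
  expect_equal(vapply(ha, `[[`, character(1), "event_type"),
               c("create", "structural_edit", "merge"))
  expect_true(all(diff(vapply(ha, `[[`, integer(1), "sequence_number")) > 0))
  expect_equal(get_record(reg, a)$status, "retired")
  expect_error(get_history(reg, "Vitvi09g00099"),
               class = "registry_unknown_id_error")
})

test_that("replaying the event log reproduces the registry state exactly", {
  for (seed in 1:5) {
    run <- random_lifecycle(seed, n_ops = 30)
    reg <- run$registry
    replayed <- replay_events(reg$events, taxon = reg$taxon,
                              base_counters = reg$base_counters)
    expect_identical(registry_state(replayed), registry_state(reg))
  }
})

test_that("identifiers are never reused over random lifecycle sequences", {
  for (seed in 1:20) {
    run <- random_lifecycle(seed, n_ops = 30)
    expect_equal(anyDuplicated(run$issued), 0L)
    expect_setequal(run$issued, registry_ids(run$registry))
  }
})

test_that("counters never decrease across any operation sequence", {
  run <- random_lifecycle(99, n_ops = 40)
  reg <- run$registry
  trace <- registry_new()
  prev <- trace$counters
  for (e in reg$events) {
    vitinom:::.apply_event(trace, e)
    expect_true(all(trace$counters >= prev))
    prev <- trace$counters
  }
})

test_that("every retired identifier resolves to exactly one active record", {
  run <- random_lifecycle(42, n_ops = 50)
  reg <- run$registry
  for (key in registry_ids(reg, "retired")) {
    final <- get_record(reg, key, follow_successors = TRUE)
    expect_equal(final$status, "active")
  }
})

test_that("a registry round-trips through its directory serialisation", {
  run <- random_lifecycle(7, n_ops = 25)
  reg <- run$registry
  add_synonym(reg, registry_ids(reg, "active")[1], "ADH1",
              note = "obsolete", reference = "doi:10.x/y")
  dir <- withr::local_tempdir()
  write_registry(reg, dir)
  expect_true(all(file.exists(file.path(
    dir, c("meta.json", "events.jsonl", "registry.tsv", "synonyms.tsv")))))
  back <- read_registry(dir)
  expect_identical(registry_state(back)$records, registry_state(reg)$records)
  expect_identical(back$counters, reg$counters)
})
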