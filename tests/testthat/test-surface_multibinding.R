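test_that("surface extraction honours the RASA cutoff and shrinks with it", {
  s <- make_toy_complex(n_residues = 12, contact_span = 4:9)
  rasa <- chain_rasa_table(s, "A", n_points = 240)
  s40 <- surface_residues(s, "A", cutoff = 40, rasa = rasa)
  s5 <- surface_residues(s, "A", cutoff = 5, rasa = rasa)
  s0 <- surface_residues(s, "A", cutoff = 0, rasa = rasa)
  expect_true(all(s40$rasa > 40))
  expect_true(nrow(s40) <= nrow(s5))
  expect_true(nrow(s5) <= nrow(s0))
  expect_identical(nrow(s0), sum(rasa$rasa > 0))
  # fully buried residues are never surface
  buried <- rasa[rasa$rasa == 0, ]
  expect_false(any(buried$res_id %in% s0$res_id))
})

test_that("rasa_statistics reproduces hand-computed means and SDs", {
  mk_iface <- function(pdb, contact_a, nearby_a) {
    structure(list(name = paste0(pdb, "AB"), pdb_id = pdb,
                   chain_a = "A", chain_b = "B",
                   side_a = list(contact = contact_a, nearby = nearby_a),
                   side_b = list(contact = character(), nearby = character())),
              class = "piface_interface")
  }
  rasa_tab <- function(ids, vals) {
    data.frame(res_id = ids, rasa = vals, stringsAsFactors = FALSE)
  }
  tables <- list(
    P1 = list(A = rasa_tab(c("A:1", "A:2", "A:3"), c(60, 40, 20)),
              B = rasa_tab(character(), numeric())),
    P2 = list(A = rasa_tab(c("A:1", "A:2", "A:3"), c(80, 40, 30)),
              B = rasa_tab(character(), numeric())))
  ifaces <- list(mk_iface("P1", c("A:1", "A:2"), "A:3"),
                 mk_iface("P2", c("A:1", "A:2"), "A:3"))
  st <- rasa_statistics(ifaces, tables)
  # per-interface contact means: 50 and 60; nearby: 20 and 30
  expect_equal(unname(st["interface_mean"]), 55)
  expect_equal(unname(st["interface_sd"]), sd(c(50, 60)))
  expect_equal(unname(st["nearby_mean"]), 25)
  expect_equal(unname(st["nearby_sd"]), sd(c(20, 30)))
  one <- rasa_statistics(ifaces[1], tables)
  expect_equal(unname(one["interface_sd"]), 0)
})

test_that("nearby residues are more buried than contacts on toy complexes", {
  s <- make_toy_complex()
  iface <- extract_first_interface(s)
  tables <- setNames(list(lapply(setNames(nm = c("A", "B")), function(ch)
    chain_rasa_table(s, ch, n_points = 240))), s$pdb_id)
  st <- rasa_statistics(list(iface), tables)
  expect_true(is.finite(st["interface_mean"]))
  expect_gt(st["interface_mean"], 0)
})

test_that("sequence clusters group exactly identical strings", {
  seqs <- c("1ABC:A" = "MKV", "1ABC:B" = "MKV", "2XYZ:A" = "MKL",
            "2XYZ:B" = "MKV", "3DEF:A" = "GGG")
  cl <- sequence_identity_clusters(seqs)
  expect_identical(unname(cl["1ABC:A"]), unname(cl["1ABC:B"]))
  expect_identical(unname(cl["1ABC:A"]), unname(cl["2XYZ:B"]))
  expect_false(cl[["1ABC:A"]] == cl[["2XYZ:A"]])
  expect_length(unique(cl), 3L)
  expect_error(sequence_identity_clusters(c(x = "")), "empty sequence")
})

test_that("chain_sequence converts residues in order", {
  s <- filter_structure(load_structure(mini_two_chain_pdb()))
  expect_identical(chain_sequence(s, "A"), "GA")
  expect_identical(chain_sequence(s, "B"), "SV")
})

mk_named_iface <- function(pdb, chain_a = "A", chain_b = "B",
                           contact_a = paste0(chain_a, ":", 1:6),
                           contact_b = paste0(chain_b, ":", 1:6)) {
  structure(list(name = paste0(pdb, chain_a, chain_b), pdb_id = pdb,
                 chain_a = chain_a, chain_b = chain_b,
                 side_a = list(contact = contact_a, nearby = character()),
                 side_b = list(contact = contact_b, nearby = character())),
            class = "piface_interface")
}

test_that("multi-interface pairs are detected by structural-cluster spread", {
  ifaces <- list(mk_named_iface("PD1"), mk_named_iface("PD2"),
                 mk_named_iface("PD3"), mk_named_iface("PD4"))
  seq_cl <- setNames(rep(1L, 8),
                     as.vector(outer(paste0("PD", 1:4), c(":A", ":B"), paste0)))
  # same pair, 3 planted structural clusters over 4 interfaces
  str_cl <- c(PD1AB = 1L, PD2AB = 1L, PD3AB = 2L, PD4AB = 3L)
  prof <- detect_multi_interface_pairs(ifaces, seq_cl, str_cl)
  expect_length(prof, 1L)
  expect_identical(prof[[1]]$pair_label, "1_1")
  expect_true(prof[[1]]$multi_interface)
  expect_identical(prof[[1]]$structural_clusters, 1:3)
  # one structural cluster -> not multi-interface
  uni <- detect_multi_interface_pairs(ifaces[1:2], seq_cl,
                                      c(PD1AB = 7L, PD2AB = 7L))
  expect_false(uni[[1]]$multi_interface)
})

test_that("pair labels are order-invariant in the chain assignment", {
  i1 <- mk_named_iface("QQ1")
  i2 <- mk_named_iface("QQ2")
  seq_fwd <- c("QQ1:A" = 4L, "QQ1:B" = 9L, "QQ2:A" = 9L, "QQ2:B" = 4L)
  prof <- detect_multi_interface_pairs(list(i1, i2), seq_fwd,
                                       c(QQ1AB = 1L, QQ2AB = 2L))
  expect_length(prof, 1L)
  expect_identical(prof[[1]]$pair_label, "4_9")
})

test_that("binding sites classify by contact overlap on the common monomer", {
  # three identical-sequence homodimer entries; two share a site, one distinct
  base <- make_toy_complex(n_residues = 24, contact_span = 5:12)
  shifted <- make_toy_complex(n_residues = 24, contact_span = 15:22)
  s1 <- base; s1$pdb_id <- "SS01"
  s2 <- perturb_interface(base, sigma = 0.2, fraction_displaced = 0.3, seed = 8)
  s2$pdb_id <- "SS02"
  s3 <- shifted; s3$pdb_id <- "SS03"
  structures <- list(SS01 = s1, SS02 = s2, SS03 = s3)
  ifaces <- lapply(structures, extract_first_interface)
  names(ifaces) <- vapply(ifaces, `[[`, character(1), "name")
  seq_cl <- sequence_identity_clusters(do.call(c, unname(
    lapply(structures, function(s)
      setNames(vapply(c("A", "B"), function(ch) chain_sequence(s, ch),
                      character(1)),
               paste0(s$pdb_id, ":", c("A", "B")))))))
  profile <- structure(list(pair_label = paste0(min(seq_cl), "_", min(seq_cl)),
                            interfaces = sort(names(ifaces)),
                            structural_clusters = 1:2,
                            multi_interface = TRUE),
                       class = "piface_pair_profile")
  res <- classify_binding_sites(profile, ifaces, structures, seq_cl)
  expect_identical(res$n_sites, 2L)
  expect_identical(res$site_of[["SS01AB"]], res$site_of[["SS02AB"]])
  expect_false(res$site_of[["SS01AB"]] == res$site_of[["SS03AB"]])
  # identical contact sets -> overlap 1 (shared); disjoint -> 0 (distinct)
  sp <- res$shared_pairs
  row12 <- sp[sp$iface1 == "SS01AB" & sp$iface2 == "SS02AB", ]
  expect_identical(row12$class, "shared")
  row13 <- sp[sp$iface1 == "SS01AB" & sp$iface2 == "SS03AB", ]
  expect_identical(row13$class, "distinct")
  # sites partition the profile's interfaces
  expect_setequal(names(res$site_of), profile$interfaces)
})
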