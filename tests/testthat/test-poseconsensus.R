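test_that("contact detection respects the cutoff boundary", {
  atoms <- data.frame(chain = "A", resno = 1, resname = "GLY", elety = "CA",
                      x = 0, y = 0, z = 0, stringsAsFactors = FALSE)
  s <- structure_model(atoms)
  expect_equal(nrow(contact_residues(s, matrix(c(3.5, 0, 0), 1), cutoff = 3.6)), 1)
  expect_equal(nrow(contact_residues(s, matrix(c(3.7, 0, 0), 1), cutoff = 3.6)), 0)
  expect_error(contact_residues(s, matrix(numeric(0), 0, 3)), "no atoms")
  expect_error(contact_residues(s, matrix(0, 1, 3), cutoff = -1), "positive")
})

test_that("grid-accelerated contacts equal the all-pairs oracle on random fixtures", {
  set.seed(8)
  for (i in 1:50) {
    fx <- random_contact_fixture(n_atoms = 200, n_pose = 10, box = 25)
    cutoff <- runif(1, 2, 6)
    grid <- sort(contact_residues(fx$structure, fx$pose, cutoff, method = "grid")$resno)
    brute <- sort(contact_residues(fx$structure, fx$pose, cutoff, method = "brute")$resno)
    oracle <- oracle_contact_resnos(fx$structure, fx$pose, cutoff)
    expect_identical(grid, oracle)
    expect_identical(brute, oracle)
  }
})

test_that("contact surfaces grow monotonically with the cutoff", {
  set.seed(9)
  fx <- random_contact_fixture(n_atoms = 300, n_pose = 15, box = 30)
  prev <- integer(0)
  for (cutoff in c(2, 3, 3.6, 5, 8)) {
    cur <- contact_residues(fx$structure, fx$pose, cutoff)$resno
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("conservation scores follow the frequency definition", {
  g <- gen_pose_ensemble(n_residues = 40, pocket_size = 5, n_poses = 1,
                         jitter = 0, seed = 10)
  cp <- conservation_scores(g$structure, g$ensemble, top_k = 1)
  expect_true(all(cp$scores$score %in% c(0, 1)))
  touched <- cp$scores[cp$scores$score == 1, ]
  cs <- contact_residues(g$structure, g$ensemble$poses[[1]])
  expect_setequal(touched$resno, cs$resno)

  # a residue hit in exactly half of the kept poses scores 0.5: build an
  # ensemble where even-numbered poses are displaced out of range
  base <- gen_pose_ensemble(n_residues = 30, pocket_size = 4, n_poses = 1,
                            jitter = 0, seed = 11)
  near <- base$ensemble$poses[[1]]
  far <- near + matrix(rep(c(0, 100, 0), each = nrow(near)), ncol = 3)
  ens <- pose_ensemble(c(rep(list(near), 25), rep(list(far), 25)),
                       energies = seq_len(50))
  cp2 <- conservation_scores(base$structure, ens, top_k = 50)
  pocket_scores <- cp2$scores$score[cp2$scores$resno %in% base$truth$resno]
  expect_true(all(pocket_scores == 0.5))
  expect_error(conservation_scores(base$structure, ens, top_k = 0), "at least 1")
})

test_that("only the top-k lowest-energy poses are scored, ties by input order", {
  g <- gen_pose_ensemble(n_residues = 30, pocket_size = 4, n_poses = 1,
                         jitter = 0, seed = 12)
  near <- g$ensemble$poses[[1]]
  far <- near + matrix(rep(c(0, 100, 0), each = nrow(near)), ncol = 3)
  # far poses have lower energy, so top-2 must pick them and score zero
  ens <- pose_ensemble(list(near, far, far, near),
                       energies = c(5, 1, 2, 6))
  cp <- conservation_scores(g$structure, ens, top_k = 2)
  expect_true(all(cp$scores$score == 0))
  expect_equal(cp$n_poses_used, 2)
})

test_that("a planted pocket is recovered as the top-ranked region", {
  g <- gen_pose_ensemble(n_residues = 120, pocket_size = 8, n_poses = 60,
                         jitter = 0.5, seed = 13)
  cp <- conservation_scores(g$structure, g$ensemble, top_k = 50)
  top <- cp$regions[1, ]
  expect_equal(top$start, min(g$truth$resno))
  expect_equal(top$end, max(g$truth$resno))
})

test_that("conservation scores are invariant under joint rigid-body motion", {
  set.seed(14)
  g <- gen_pose_ensemble(n_residues = 60, pocket_size = 6, n_poses = 20,
                         jitter = 0.8, seed = 15)
  cp1 <- conservation_scores(g$structure, g$ensemble, top_k = 15)
  tf <- random_rigid_transform()
  s2 <- apply_transform_structure(g$structure, tf)
  ens2 <- pose_ensemble(lapply(g$ensemble$poses, tf), g$ensemble$energies)
  cp2 <- conservation_scores(s2, ens2, top_k = 15)
  expect_equal(cp1$scores$score, cp2$scores$score)
  expect_equal(cp1$regions$start, cp2$regions$start)
})

test_that("interface residues are symmetric and track constructed geometry", {
  atoms <- data.frame(
    chain = c("A", "A", "B", "B"),
    resno = c(1, 2, 10, 11), resname = "ALA", elety = "CA",
    x = c(0, 50, 3, 80), y = 0, z = 0, stringsAsFactors = FALSE)
  s <- structure_model(atoms)
  # exactly one atom pair at 3.0 A
  pairs <- interface_residues(s, "A", "B", cutoff = 3.6)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$resno_a, 1)
  expect_equal(pairs$resno_b, 10)
  # mirror symmetry
  rev <- interface_residues(s, "B", "A", cutoff = 3.6)
  expect_equal(rev$resno_a, pairs$resno_b)
  expect_equal(rev$resno_b, pairs$resno_a)
  # chains far apart: empty set
  atoms2 <- atoms; atoms2$x[atoms2$chain == "B"] <- atoms2$x[atoms2$chain == "B"] + 500
  expect_equal(nrow(interface_residues(structure_model(atoms2), "A", "B")), 0)
  expect_error(interface_residues(s, "A", "Z"), "chain 'Z'")
})

test_that("site overlap reports shared residues, Jaccard and center separation", {
  g <- gen_pose_ensemble(n_residues = 40, pocket_size = 5, n_poses = 1,
                         jitter = 0, seed = 16)
  pose <- g$ensemble$poses[[1]]
  site <- contact_residues(g$structure, pose)
  ident <- site_overlap(site, site, pose, pose)
  expect_equal(ident$jaccard, 1)
  expect_equal(ident$center_distance, 0)
  # 3-4-5 construction: translating the ligand by (0.3, 0.4, 0) moves the
  # geometric center by exactly 0.5 A
  shifted <- sweep(pose, 2, c(0.3, 0.4, 0), "+")
  ov <- site_overlap(site, site, pose, shifted)
  expect_equal(ov$center_distance, 0.5)
  # disjoint sites
  other <- data.frame(chain = "A", resno = 99, resname = "ALA")
  expect_equal(site_overlap(site, other, pose, pose)$jaccard, 0)
  empty <- site[0, ]
  expect_true(is.na(site_overlap(empty, empty, pose, pose)$jaccard))
})

test_that("poses split between two sites score both regions near one half", {
  g <- gen_pose_ensemble(n_residues = 100, pocket_size = 6, pocket_start = 20,
                         n_poses = 1, jitter = 0, seed = 17)
  g2 <- gen_pose_ensemble(n_residues = 100, pocket_size = 6, pocket_start = 70,
                          n_poses = 1, jitter = 0, seed = 17)
  poses <- c(rep(g$ensemble$poses, 20), rep(g2$ensemble$poses, 20))
  ens <- pose_ensemble(poses, energies = seq_len(40))
  cp <- conservation_scores(g$structure, ens, top_k = 40)
  expect_equal(nrow(cp$regions), 2)
  expect_equal(cp$regions$mean_score, c(0.5, 0.5))
})
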