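test_that("contact counting respects the cutoff boundary", {
  mk <- function(d) {
    new_frame(tibble::tibble(
      role = c("LYS_NZ", "LIPID_P"), chain = c("P1", "L1"),
      resid = 1L, resname = c("LYS", "POP"),
      x = c(0, d), y = 0, z = 0
    ))
  }
  expect_equal(count_contacts(mk(4.5), "lys_phosphate"), 1)
  expect_equal(count_contacts(mk(4.6), "lys_phosphate"), 1) # at the cutoff
  expect_equal(count_contacts(mk(4.7), "lys_phosphate"), 0)
  # absent roles yield zero, not an error
  expect_equal(count_contacts(mk(4.5), "lys_glu"), 0)
})

test_that("minimum-image wrapping applies only on periodic axes", {
  fr <- new_frame(
    tibble::tibble(
      role = c("LYS_NZ", "LIPID_P"), chain = c("P1", "L1"),
      resid = 1L, resname = c("LYS", "POP"),
      x = c(1, 19), y = 0, z = 0
    ),
    box = c(20, 20, 20), periodic = c(TRUE, FALSE, FALSE)
  )
  # wrapped separation is 2 Angstrom
  expect_equal(count_contacts(fr, "lys_phosphate"), 1)
  attr(fr, "periodic") <- c(FALSE, FALSE, FALSE)
  expect_equal(count_contacts(fr, "lys_phosphate"), 0)
  # cutoffs at or above half the periodic box length are rejected
  small <- fr
  attr(small, "periodic") <- c(TRUE, FALSE, FALSE)
  attr(small, "box") <- c(9, 20, 20)
  expect_error(count_contacts(small, "lys_phosphate"), "half the periodic")
})

test_that("contact counts equal the brute-force oracle on random fixtures", {
  set.seed(42)
  for (rep in 1:50) {
    periodic <- c(rep %% 2 == 0, rep %% 3 == 0, FALSE)
    fr <- random_two_role_frame(50, "LYS_NZ", "LIPID_P",
      box = c(20, 20, 20), periodic = periodic
    )
    expect_identical(
      count_contacts(fr, "lys_phosphate"),
      oracle_count_contacts(fr, "LYS_NZ", "LIPID_P", 4.6)
    )
  }
  # same-role spec: unordered pairs, intra-residue excluded
  for (rep in 1:50) {
    fr <- random_two_role_frame(50, "LEU_SIDECHAIN_C", "LEU_SIDECHAIN_C",
      box = c(25, 25, 25), periodic = c(rep %% 2 == 0, FALSE, FALSE)
    )
    expect_identical(
      count_contacts(fr, "leu_leu"),
      oracle_count_contacts(fr, "LEU_SIDECHAIN_C", "LEU_SIDECHAIN_C", 7.9)
    )
  }
})

test_that("pair-based counting and intra-residue exclusion", {
  # one Lys amine within cutoff of two phosphates counts two contacts
  fr <- new_frame(tibble::tibble(
    role = c("LYS_NZ", "LIPID_P", "LIPID_P"),
    chain = c("P1", "L1", "L2"), resid = 1L,
    resname = c("LYS", "POP", "POP"),
    x = c(0, 3, -3), y = 0, z = 0
  ))
  expect_equal(count_contacts(fr, "lys_phosphate"), 2)
  # atoms of the same residue never count
  fr2 <- new_frame(tibble::tibble(
    role = c("LYS_NZ", "GLU_CD"), chain = "P1", resid = c(3L, 3L),
    resname = c("LYS", "GLU"), x = c(0, 2), y = 0, z = 0
  ))
  expect_equal(count_contacts(fr2, "lys_glu"), 0)
  # same chain, different residues: counted unless excluded
  fr3 <- new_frame(tibble::tibble(
    role = c("LYS_NZ", "GLU_CD"), chain = "P1", resid = c(3L, 7L),
    resname = c("LYS", "GLU"), x = c(0, 2), y = 0, z = 0
  ))
  expect_equal(count_contacts(fr3, "lys_glu"), 1)
  expect_equal(count_contacts(fr3, "lys_glu", exclude_same_chain = TRUE), 0)
})

test_that("per-peptide contact averaging is the frame mean over peptides", {
  # alternating 0 and 4 contacts over frames, 2 peptides -> 1.0
  base <- new_frame(tibble::tibble(
    role = rep(c("LYS_NZ", "LIPID_P"), each = 4),
    chain = c(paste0("P", 1:4), paste0("L", 1:4)),
    resid = 1L, resname = rep(c("LYS", "POP"), each = 4),
    x = c(0, 50, 100, 150, 300, 350, 400, 450), y = 0, z = 0
  ))
  sched <- lapply(1:4, function(i) c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  script <- tibble::tibble(
    atom_a = 1:4, atom_b = 5:8, cutoff = 4.6, schedule = sched
  )
  traj <- synthesize_trajectory(base, 0, 6, dt = 10, contact_script = script)
  cs <- contact_series(traj, "lys_phosphate")
  expect_equal(cs$counts, rep(c(0L, 4L), 3))
  expect_equal(mean_contacts_per_peptide(traj, "lys_phosphate", 2), 1.0)
  expect_equal(mean_contacts_per_peptide(traj, "lys_phosphate", 4), 0.5)
})

test_that("lifetimes equal the run-length oracle and conserve contact-frames", {
  # hand cases
  fr <- new_frame(tibble::tibble(
    role = c("LYS_NZ", "LIPID_P"), chain = c("P1", "L1"), resid = 1L,
    resname = c("LYS", "POP"), x = c(0, 20), y = 0, z = 0
  ))
  mk_series <- function(sched, dt) {
    script <- tibble::tibble(
      atom_a = 1L, atom_b = 2L, cutoff = 4.6, schedule = list(sched)
    )
    contact_series(
      synthesize_trajectory(fr, 0, length(sched), dt,
        contact_script = script
      ),
      "lys_phosphate"
    )
  }
  expect_equal(
    suppressWarnings(contact_lifetimes(mk_series(c(TRUE, TRUE, TRUE, FALSE, TRUE), 10))),
    20
  )
  expect_equal(contact_lifetimes(mk_series(rep(TRUE, 100), 1)), 100)
  # a never-present contact gives an absent value
  expect_true(is.na(contact_lifetimes(mk_series(rep(FALSE, 5), 10))))
  # random presence matrices against the RLE oracle
  set.seed(99)
  for (rep in 1:20) {
    sched <- stats::runif(30) < 0.5
    cs <- mk_series(sched, 7)
    expect_equal(
      suppressWarnings(contact_lifetimes(cs)),
      oracle_mean_lifetime(cs$presence, 7)
    )
    # total contact-frames are conserved by the run decomposition
    expect_equal(sum(cs$presence), sum(cs$counts))
  }
  # resolution warning when the spacing exceeds the mean lifetime
  expect_warning(
    contact_lifetimes(mk_series(c(TRUE, FALSE, TRUE, FALSE), 240)),
    "resolution-limited"
  )
})

test_that("dimer classification needs evidence and reads geometry", {
  # antiparallel pair with one engineered Lys-Glu salt bridge
  fr <- two_helix_frame(antiparallel = TRUE, separation = 30)
  expect_equal(nrow(classify_dimers(fr)), 0) # no contacts at 30 Angstrom
  # move one Glu carboxyl of P2 within 4.0 Angstrom of a Lys amine of P1
  nz <- which(fr$role == "LYS_NZ" & fr$chain == "P1")[1]
  cd <- which(fr$role == "GLU_CD" & fr$chain == "P2")[1]
  fr$x[cd] <- fr$x[nz] + 4.0
  fr$y[cd] <- fr$y[nz]
  fr$z[cd] <- fr$z[nz]
  d <- classify_dimers(fr)
  expect_equal(nrow(d), 1)
  expect_equal(d$orientation, "antiparallel")
  expect_gte(d$n_salt_bridges, 1)
  # the same pair at 5.0 Angstrom is no longer evidence
  fr$x[cd] <- fr$x[nz] + 5.0
  expect_equal(nrow(classify_dimers(fr)), 0)
  # parallel orientation flips the label
  fp <- two_helix_frame(antiparallel = FALSE, separation = 30)
  nz <- which(fp$role == "LYS_NZ" & fp$chain == "P1")[1]
  cd <- which(fp$role == "GLU_CD" & fp$chain == "P2")[1]
  fp$x[cd] <- fp$x[nz] + 4.0
  fp$y[cd] <- fp$y[nz]
  fp$z[cd] <- fp$z[nz]
  expect_equal(classify_dimers(fp)$orientation, "parallel")
})

test_that("dimer register follows the axial offset of backbone centres", {
  mk <- function(z_shift) {
    fr <- two_helix_frame(antiparallel = TRUE, separation = 12,
      z_shift = z_shift
    )
    classify_dimers(fr)
  }
  # side-by-side antiparallel helices touch through Leu-Leu contacts
  aligned <- mk(0)
  expect_equal(nrow(aligned), 1)
  expect_equal(aligned$register, "matched")
  shifted <- mk(5)
  expect_equal(shifted$register, "mismatched")
})

test_that("contact evidence is pairwise, not transitive", {
  fr <- two_helix_frame(antiparallel = TRUE, separation = 40)
  c3 <- build_ideal_helix(elk_peptides()[["neu"]], chain = "P3")
  c3$x <- c3$x + 80
  fr <- new_frame(dplyr::bind_rows(tibble::as_tibble(fr), c3))
  link <- function(fr, from, to) {
    nz <- which(fr$role == "LYS_NZ" & fr$chain == from)[1]
    cd <- which(fr$role == "GLU_CD" & fr$chain == to)[1]
    fr$x[cd] <- fr$x[nz] + 3.5
    fr$y[cd] <- fr$y[nz]
    fr$z[cd] <- fr$z[nz]
    fr
  }
  fr <- link(fr, "P1", "P2")
  fr <- link(fr, "P2", "P3")
  d <- classify_dimers(fr)
  expect_setequal(paste(d$chain_a, d$chain_b), c("P1 P2", "P2 P3"))
})
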