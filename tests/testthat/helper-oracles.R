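# Independent oracles used to cross-check the package implementations.

# brute-force O(n^2) contact count: explicit double loop with per-axis
# minimum-image wrapping, independent of the vectorised implementation
oracle_count_contacts <- function(frame, role_a, role_b, cutoff,
                                  exclude_same_chain = FALSE) {
  box <- frame_box(frame)
  periodic <- frame_periodic(frame)
  ia <- which(frame$role == role_a)
  ib <- which(frame$role == role_b)
  n <- 0L
  for (i in ia) {
    for (j in ib) {
      if (role_a == role_b && i >= j) next
      if (frame$chain[i] == frame$chain[j] &&
        frame$resid[i] == frame$resid[j]) {
        next
      }
      if (exclude_same_chain && frame$chain[i] == frame$chain[j]) next
      d <- c(
        frame$x[i] - frame$x[j], frame$y[i] - frame$y[j],
        frame$z[i] - frame$z[j]
      )
      for (k in 1:3) {
        if (periodic[k]) d[k] <- d[k] - box[k] * round(d[k] / box[k])
      }
      if (sqrt(sum(d^2)) <= cutoff) n <- n + 1L
    }
  }
  n
}

# run-length-encoding lifetime oracle: mean run length of TRUE runs over
# the columns of a presence matrix, times dt
oracle_mean_lifetime <- function(presence, dt) {
  runs <- c()
  for (j in seq_len(ncol(presence))) {
    len <- 0
    for (t in seq_len(nrow(presence))) {
      if (presence[t, j]) {
        len <- len + 1
      } else if (len > 0) {
        runs <- c(runs, len)
        len <- 0
      }
    }
    if (len > 0) runs <- c(runs, len)
  }
  if (length(runs) == 0) NA_real_ else mean(runs) * dt
}

# dense-grid isoelectric point: pH of minimum |charge| on a fine grid
oracle_pi_grid <- function(sequence, step = 1e-3) {
  grid <- seq(step, 14 - step, by = step)
  q <- peptide_charge(rep(sequence, length(grid)), grid)
  grid[which.min(abs(q))]
}

# random frame with n atoms of each of two roles in a box
random_two_role_frame <- function(n, role_a, role_b, box = c(20, 20, 20),
                                  periodic = c(FALSE, FALSE, FALSE)) {
  m <- 2 * n
  new_frame(
    tibble::tibble(
      role = rep(c(role_a, role_b), each = n),
      chain = paste0(rep(c("P", "L"), each = n), seq_len(m)),
      resid = 1L, resname = rep(c("LYS", "POP"), each = n),
      x = stats::runif(m, 0, box[1]),
      y = stats::runif(m, 0, box[2]),
      z = stats::runif(m, 0, box[3])
    ),
    box = box, periodic = periodic
  )
}

# bare two-helix frame for dimer tests: helices along +/- z at a lateral
# separation, optionally shifted axially
two_helix_frame <- function(sequence = elk_peptides()[["neu"]],
                            antiparallel = TRUE, separation = 30,
                            z_shift = 0) {
  a <- build_ideal_helix(sequence, chain = "P1")
  a <- pepdisc:::orient_helix(a, sequence, face_to = 0)
  b <- build_ideal_helix(sequence, chain = "P2")
  b <- pepdisc:::orient_helix(b, sequence, face_to = 180, flip = antiparallel)
  b$x <- b$x + separation
  b$z <- b$z + z_shift
  new_frame(dplyr::bind_rows(a, b))
}
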