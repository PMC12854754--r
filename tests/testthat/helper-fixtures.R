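# Fixtures built in code: random-walk trajectory sets, exact MSD curves,
# and miniature oriented PDB files.

# Plain Gaussian random walks (no obstacles), optionally with localization
# noise; returns a trajectory_set. Starting positions uniform in `box`.
rw_tracks <- function(n_tracks, n_frames, D = 1, frame_spacing = 0.01,
                      sigma = 0, box = 10, seed = 1, mass = 500) {
  withr::with_seed(seed, {
    sl <- sqrt(2 * D * frame_spacing)
    recs <- lapply(seq_len(n_tracks), function(i) {
      x <- cumsum(c(runif(1, 0, box), rnorm(n_frames - 1, 0, sl)))
      y <- cumsum(c(runif(1, 0, box), rnorm(n_frames - 1, 0, sl)))
      data.frame(track_id = i, frame = seq_len(n_frames),
                 x_um = x + rnorm(n_frames, 0, sigma),
                 y_um = y + rnorm(n_frames, 0, sigma), mass = mass)
    })
    trajectory_set(do.call(rbind, recs), frame_spacing)
  })
}

# An msd_curve holding exact model values MSD = 4 D (t - t_ill/3) + 4 s^2.
exact_msd_curve <- function(D, sigma, t_ill, lags = 1:2,
                            frame_spacing = 0.01) {
  t <- lags * frame_spacing
  structure(list(lag_times = t,
                 msd = 4 * D * (t - t_ill / 3) + 4 * sigma^2,
                 n_pairs = rep(100L, length(lags)),
                 frame_spacing = frame_spacing,
                 n_trajectories = 10L),
            class = "msd_curve")
}

pdb_line <- function(type, serial, name, resn, chain, resno, x, y, z, elem) {
  sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, resn, chain, resno, x, y, z, 1, 0, elem)
}

# Write a minimal oriented PDB: atoms given as data.frame(elem, x, y, z),
# plus DUM markers at +/- z_top when dum = TRUE.
write_mini_pdb <- function(atoms, path = tempfile(fileext = ".pdb"),
                           z_top = 15, dum = TRUE, waters = 0) {
  lines <- mapply(function(i, e, x, y, z)
    pdb_line("ATOM", i, e, "ALA", "A", i, x, y, z, e),
    seq_len(nrow(atoms)), atoms$elem, atoms$x, atoms$y, atoms$z)
  n <- nrow(atoms)
  if (waters > 0) {
    lines <- c(lines, sapply(seq_len(waters), function(i)
      pdb_line("HETATM", n + i, "O", "HOH", "A", n + i, 50 + i, 50, 5, "O")))
    n <- n + waters
  }
  if (dum) {
    lines <- c(lines,
               pdb_line("HETATM", n + 1, "N", "DUM", "B", 9998, 0, 0, z_top, "N"),
               pdb_line("HETATM", n + 2, "N", "DUM", "B", 9999, 0, 0, -z_top, "N"))
  }
  writeLines(c(lines, "END"), path)
  path
}

# Independent scalar evaluation of the inert-obstacle mobility model,
# written out stepwise (used to cross-check the packaged implementation).
oracle_inert <- function(rho, R_nm, cp = 0.676) {
  R_um <- R_nm / 1000
  filling <- rho * pi * R_um^2
  1 - sqrt(1 - exp(-filling / cp))
}
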