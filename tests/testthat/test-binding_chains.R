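test_that("chain_intervals reproduces the scalar examples", {
  # association triggers at 5 A, frame 4 exceeds 10 A
  expect_equal(chain_intervals(c(12, 8, 5, 7, 11)),
               data.frame(start = 2L, end = 3L, terminated = TRUE))
  # never associates
  expect_equal(nrow(chain_intervals(c(12, 15, 11))), 0)
  # never dissociates -> unterminated chain
  expect_equal(chain_intervals(c(5, 5, 5)),
               data.frame(start = 0L, end = 2L, terminated = FALSE))
  expect_error(chain_intervals(c(5, 5), assoc_cutoff = 10, dissoc_cutoff = 6),
               "smaller")
})

test_that("hysteresis band neither opens nor closes chains", {
  # oscillation in (6, 10] after a chain opened: chain survives throughout
  d <- c(12, 5, 7, 9.5, 6.5, 9.9, 7, 11)
  iv <- chain_intervals(d)
  expect_equal(iv, data.frame(start = 1L, end = 6L, terminated = TRUE))
  # oscillation in (6, 10] with no prior association: nothing opens
  d2 <- c(12, 8, 9.5, 6.5, 7, 9.9, 12)
  expect_equal(nrow(chain_intervals(d2)), 0)
  # two well-separated visits -> two chains
  d3 <- c(12, 5, 11, 12, 4, 12)
  iv3 <- chain_intervals(d3)
  expect_equal(iv3$start, c(1L, 4L))
  expect_equal(iv3$end, c(1L, 4L))
})

test_that("is_docked evaluates both carboxylate orientations", {
  nh1 <- c(0, 1.1, 0); nh2 <- c(0, -1.1, 0)
  # Condition 1: NH1-OT1 3.5, NH2-OT2 3.8
  expect_true(is_docked(nh1, nh2, nh1 + c(3.5, 0, 0), nh2 + c(3.8, 0, 0)))
  # Condition 2 (flipped): NH2-OT1 3.0, NH1-OT2 3.9, cond-1 pairs far
  expect_true(is_docked(nh1, nh2, nh2 + c(0, -3, 0), nh1 + c(0, 3.9, 0)))
  # one pair inside, partner outside, flipped pairs far -> not docked
  expect_false(is_docked(nh1, nh2, nh1 + c(3.5, 0, 0), nh2 + c(4.5, 0, 0)))
  expect_error(is_docked(nh1, nh2, c(NA, 0, 0), nh2), "unresolved")
})

test_that("detect_chains matches the brute-force oracle on scripted geometry", {
  # ligand slides in, lingers, docks, and leaves; extra decoy residues
  gaps <- c(30, 20, 12, 8, 5, 4.1, 4.1, 7, 9, 13, 30, 25, 6, 30)
  traj <- mini_traj(gaps, n_extra_residues = 2)
  got <- detect_chains(traj, 0)
  want <- oracle_detect(traj, 0)
  expect_equal(length(got), length(want))
  for (i in seq_along(got)) {
    expect_equal(got[[i]]$start_frame, want[[i]]$start)
    expect_equal(got[[i]]$end_frame, want[[i]]$end)
    expect_equal(got[[i]]$terminated, want[[i]]$terminated)
    expect_equal(got[[i]]$docked_frames, want[[i]]$docked_frames)
  }
  expect_error(detect_chains(traj, 0, assoc_cutoff = 10, dissoc_cutoff = 6),
               "smaller")
})

test_that("split_chain follows the first/last-dock rule", {
  # long chain with an internal docked block
  gaps <- c(rep(30, 2), seq(12, 4.2, length.out = 5), rep(4.1, 4),
            rep(8, 3), rep(4.1, 2), seq(8, 30, length.out = 4))
  traj <- mini_traj(gaps)
  ch <- detect_chains(traj, 0)[[1]]
  expect_gt(length(ch$docked_frames), 0)
  ps <- split_chain(ch, traj)
  expect_length(ps, 2)
  bind <- ps[[1]]; unbind <- ps[[2]]
  expect_equal(bind$direction, "binding")
  expect_equal(bind$frames, ch$start_frame:min(ch$docked_frames))
  expect_equal(unbind$direction, "unbinding-reversed")
  expect_equal(unbind$frames, ch$end_frame:max(ch$docked_frames))
  # traces follow the stored frame order (unbinding reversed in time)
  ref_row <- which(traj$top$atoms$atom_id == traj$top$ligand_ref_atom[1])
  expect_equal(unbind$trace[1, ], traj$coords[ch$end_frame + 1, ref_row, ])
  # binding and unbinding overlap only at docked frames
  expect_true(all(intersect(bind$frames, unbind$frames) %in% ch$docked_frames))
})

test_that("split_chain discards undocked chains and truncated ends", {
  # never docks: carboxylate-guanidinium separation stays in (4, 6]
  traj <- mini_traj(c(30, 8, 7.5, 8, 30))
  ch <- detect_chains(traj, 0)[[1]]
  expect_length(ch$docked_frames, 0)
  expect_length(split_chain(ch, traj), 0)
  # docked exactly at the final frame of a terminated chain
  gaps2 <- c(30, 8, 5, 4.1, 30)
  traj2 <- mini_traj(gaps2)
  ch2 <- detect_chains(traj2, 0)[[1]]
  expect_equal(max(ch2$docked_frames), ch2$end_frame)
  expect_length(split_chain(ch2, traj2), 1)
  # unterminated chain: binding pathway only
  gaps3 <- c(30, 8, 5, 4.1, 4.1, 6)
  traj3 <- mini_traj(gaps3)
  ch3 <- detect_chains(traj3, 0)[[1]]
  expect_false(ch3$terminated)
  ps3 <- split_chain(ch3, traj3)
  expect_length(ps3, 1)
  expect_equal(ps3[[1]]$direction, "binding")
})

test_that("classify_mechanism counts distinct pre-dock surface residues", {
  mk_path <- function(contacts_by_frame) {
    structure(list(direction = "binding",
                   frames = seq_along(contacts_by_frame) - 1L,
                   per_frame_contacts = contacts_by_frame),
              class = "lp_pathway")
  }
  # only the docking residue before docking -> free
  p0 <- mk_path(list(518L, 518L, 518L))
  expect_equal(as.character(classify_mechanism(p0, exclude_residues = 518L)),
               "free")
  # eight distinct surface residues -> guided at the default threshold
  p8 <- mk_path(list(c(401L, 402L), c(403L, 404L), c(405L, 406L, 407L, 408L),
                     518L))
  expect_equal(as.character(classify_mechanism(p8, exclude_residues = 518L)),
               "guided")
  expect_equal(attr(classify_mechanism(p8, exclude_residues = 518L),
                    "n_surface_residues"), 8L)
  # threshold 1: any docked pathway with at least one contact is guided
  expect_equal(as.character(classify_mechanism(p0, min_distinct_residues = 1)),
               "guided")
})

test_that("association census conserves counts and screens residues", {
  rec <- make_toy_receptor(seed = 5, n_residues = 30, n_copies = 2)
  sim <- simulate_binding(rec, n_frames = 350, dt = 0.2, seed = 9,
                          mode = "guided", rate_per_ns = 0.06)
  cen <- association_census(sim$trajectory)
  expect_gt(cen$n_associations, 0)
  n_undocked <- sum(vapply(cen$chains,
                           function(ch) length(ch$docked_frames) == 0, logical(1)))
  expect_equal(cen$n_associations, cen$n_docked + n_undocked)
  expect_equal(cen$associations_per_us,
               cen$n_associations / (cen$duration_ns / 1000))
  pr <- cen$per_residue
  expect_true(all(pr$n_success <= pr$n_associations))
  expect_equal(pr$success_pct, 100 * pr$n_success / pr$n_associations)
  # 3 chains / 1 docked style fraction check on a tiny crafted example:
  # residues contacted in every chain have success fraction n_docked/n_assoc
  everywhere <- pr[pr$n_associations == cen$n_associations, ]
  if (nrow(everywhere) > 0)
    expect_equal(unique(everywhere$n_success), cen$n_docked)
  expect_error(association_census(
    lp_trajectory(sim$trajectory$coords[1, , , drop = FALSE],
                  sim$trajectory$top)), "zero duration")
})
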