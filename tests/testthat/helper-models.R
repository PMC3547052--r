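# Shared builders for solver and pipeline tests.

# straight single-element beam along +Z, fixed at the origin node
cantilever <- function(len = 10, d = 1, E = 200000, nu = 0.25) {
  nodes <- rbind(root = c(0, 0, 0), tip = c(0, 0, len))
  el <- data.frame(label = "beam", from = "root", to = "tip", diameter = d)
  frame_model(nodes, el, material(E, nu))
}

tip_force <- function(fx = 0, fy = 0, fz = 0) {
  load_case("tip", forces = data.frame(node = "tip", fx = fx, fy = fy,
                                       fz = fz),
            restraints = list(root = TRUE))
}

tip_moment <- function(mx = 0, my = 0, mz = 0) {
  load_case("tip", moments = data.frame(node = "tip", mx = mx, my = my,
                                        mz = mz),
            restraints = list(root = TRUE))
}

taxa_measurements <- function() packaged_measurements("taxa")

taxa_models <- function(m = taxa_measurements()) {
  lapply(seq_len(nrow(m)), function(i) build_beam_frame(m[i, ]))
}

# ranked taxon abbreviations for one load case of a strain table
ranked_abbrevs <- function(strains, case, measurements = taxa_measurements()) {
  r <- rank_performance(strains)
  r <- r[r$load_case == case, ]
  measurements$abbrev[match(r$taxon, measurements$taxon)]
}
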