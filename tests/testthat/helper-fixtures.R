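# Shared fixtures: built in code at test time, never stored on disk.

default_model <- function(...) build_default_int(...)

# a small irregular model exercising unequal interbands and widths
irregular_model <- function(speed_mode = "dna") {
  chromosome_model(data.frame(
    name = c("bL", "i1", "g1", "i2", "mg", "i3", "bR"),
    kind = c("black", "interband", "gray", "interband", "middle_gray",
             "interband", "black"),
    dna_kbp = c(40, 1.5, 7, 3, 12, 2, 60),
    axial_width = c(0.8, 1, 1.2, 0.9, 1, 1.1, 1.5)
  ), speed_mode)
}

sync_records <- function(seed = 1, n = 1024, model = default_model()) {
  simulate_replication(model, initiation_scenario(0), n, 2, seed = seed)
}

# closed-form dna-mode fork position: origin +/- v*(t-a), clamped
dna_fork_closed <- function(model, g0, elapsed, dir, speed = 2) {
  pmin(pmax(g0 + dir * speed * elapsed, 0), total_genomic(model))
}
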