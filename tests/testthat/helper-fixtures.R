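# Shared fixtures built in code.

default_geom <- lead_geometry("sensight-short")

all_segments <- c("1A", "1B", "1C", "2A", "2B", "2C")

# A quick synthetic survey with the source near a given contact.
quick_sim <- function(target = "2B", snr = 4, seed = 1,
                      geom = default_geom, ...) {
  simulate_survey(source_model(source_near_segment(geom, target), ...),
                  noise_model(), geom, snr = snr, seed = seed)
}

# Survey where every channel carries the same given samples.
uniform_survey <- function(samples, fs = 250, geom = default_geom) {
  recs <- stats::setNames(rep(list(samples), length(montage_pairs())),
                          montage_pairs())
  new_hemisphere_survey(recs, fs = fs, geometry = geom)
}
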