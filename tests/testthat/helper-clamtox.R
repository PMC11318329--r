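# worked lesion-score example used across histopathology tests:
# weighted numerator 1*2 + 2*4 + 3*0 + 1*2 + 1*0 + 2*2 + 3*6 = 34, over 78
example_scores <- c(
  vacuolation = 2, tubular_atrophy = 4, tubular_necrosis = 0,
  hemocyte_infiltration = 2, brown_cells = 0, fibrosis = 2,
  intertubular_necrosis = 6
)

# minimal comet cell: head of 10 bins (total 80), tail of 10 bins (total 20),
# bin width 1 um, head boundary at 10 um
example_comet_cell <- function() {
  comet_cell(position = 1:20,
             intensity = c(rep(8, 10), rep(2, 10)),
             head_boundary = 10)
}

# survival records built directly from times/events for hand-sized oracles
make_survival <- function(group, day, event) {
  data.frame(individual_id = sprintf("i%02d", seq_along(day)),
             group = group, aquarium = 1L, day = day, event = event,
             stringsAsFactors = FALSE)
}
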