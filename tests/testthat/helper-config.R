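# Tiny dissection configuration for fast orchestration tests: a 60 mm
# dissected segment on the coarse mesh, with the time step chosen so the
# convective CFL stays below ~0.5 at the default waveform's systolic peak.
tiny_run_config <- function(...) {
  mini_dissection_config(
    geometry = list(dissected_length = 60, inlet_extension = 10,
                    outlet_extension = 10,
                    entry_tear_center = 17.5, reentry_tear_center = 62.5),
    waveform = list(mean_velocity = 0.12),
    run = list(pre_cycles = 0, cycles = 1, steps_per_cycle = 1600,
               chunks_per_cycle = 2),
    ...)
}
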