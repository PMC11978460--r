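# Example traplinr run configuration. Every key is optional; omitted keys
# take the defaults shown here (see ?default_config). Unknown keys are
# rejected so typos fail loudly.

environment:
  layout: uniform        # "uniform" or "patch"
  n_sites: 25            # feeding sites in the arena / patch
  arena_side: 500        # square arena side, metres (nest at the centre)
  # density: 0.002       # patch layouts only: sites per square metre
  n_max: 20              # maximal nectar load per site, microlitres
  renewal_duration: 1500 # seconds to refill a site from empty to full

bee:
  alpha: 0.5             # learning rate, 0 (no learning) .. 1 (replace)
  beta: 20               # softmax sharpness; 0 = uniform random choice
  wm_span: 30            # working-memory span, seconds; or "matched" to
                         # tie it to the nectar renewal duration
  speed: 3               # flight speed, metres per second
  max_bout_distance: 3000  # flight budget per bout, metres
  nest_wait: 300         # pause in the nest between bouts, seconds
  value_basis: standing  # value nectar present on arrival ("standing")
                         # or the amount actually collected ("collected")

simulation:
  n_bees: 1              # foragers sharing the environment
  horizon: 25200         # simulated foraging time, seconds (7 h)
  dt: 1                  # timestep, seconds
  rng_seed: 1            # master seed; all streams derive from it
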