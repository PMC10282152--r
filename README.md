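# memwm

Simulation of a memristor-based spiking neural network that realises the
two functional states of working memory: a **focused** state, in which a
remembered item is expressed as sustained firing of a single
freely-conjunctive neuron, and an **unfocused** (activity-silent) state,
in which the item persists only in synaptic conductances and can be
reactivated by a partial cue.

The package is for computational-neuroscience and neuromorphic-hardware
researchers who want a self-contained, deterministic desk-scale model of
how nonlinear memristive devices can implement Hebbian working memory —
from the single-device physics up to the behavioural task.

## The model

**Device.** A threshold memristor with state $x \in [0,1]$:

$$I = a_{1,2}\Big(\tfrac1r + \tfrac{(r-1)\,x}{r}\Big)\sinh(bV),\qquad
\dot x = \eta\, g(V)\, f(x),$$

where $g(V)$ is zero on the dead zone $[-V_n, V_p]$ and exponential
beyond the programming thresholds, and $f(x)$ is a window function that
confines the state to $[0,1]$. The parameter $r$ bounds the resistance
range (highest/lowest = 9 for the default Au/LNO/Pt device constants).
The normalised conductance serves as the synaptic weight.

**Plasticity.** A simplified timing-window Hebbian rule: a
post-synaptic spike within 2 ms after a pre-synaptic spike elicits LTP,
otherwise LTD; each decision is one SET (width $3T_p$, positive) or
RESET (width $T_p$, negative) pulse on the synapse's memristor, with
$T_p = 1$ ms.

**Network.** 9 feature-selective LIF neurons (3 dimensions × 3
features) and 3 freely-conjunctive LIF neurons, fully bipartitely
connected in both directions with plastic memristive synapses
(27 + 27), plus 6 fixed lateral-inhibition synapses and 3 fixed
self-excitatory synapses implementing winner-takes-all competition.

## Worked example

Characterise the device, then run the full three-object working-memory
experiment with a colour-only retrieval cue:

```r
library(memwm)

p <- memristor_params()                  # fitted device constants
ltp <- run_pulse_train(memristor_state(p = p), pulse_train(), p)
head(ltp, 3)
#> # A tibble: 3 × 4
#>   pulse_index voltage_V width_ms conductance_S
#>         <int>     <dbl>    <dbl>         <dbl>
#> 1           1       1.5        5   0.000000139
#> 2           2       1.5        5   0.000000152
#> 3           3       1.5        5   0.000000164
read_conductance(1, p) / read_conductance(0, p)
#> [1] 9                                  # resistance ratio r, exactly

ex <- run_experiment(seed = 2)           # encode Obj1..Obj3, cue "red"
tidy(ex)
#> # A tibble: 4 × 9
#>   epoch     t_from  t_to state   winner top_rate_hz ...
#> 1 post-Obj1    155   185 focused C2           133.
#> 2 post-Obj2    305   335 focused C2           100
#> 3 post-Obj3    455   485 focused C2            33.3
#> 4 pre-cue      460   500 none    <NA>           0
ex$retrieval[[1]]
#> <wm_retrieval> Obj1: SUCCESS (target neuron refocused and
#>                non-cued features reactivated)
```

`tidy(ex)` reports, for each post-stimulus rest epoch, whether exactly
one conjunctive neuron kept firing above 20 Hz after the stimulus was
withdrawn (the focused state), which neuron won, and the strongest
object-to-neuron mapping held silently in the forward weights. The
retrieval record shows whether the single-feature cue ("red")
re-ignited the neuron mapped to Obj1 and re-activated its non-cued
features (associative completion).

Plots: `plot_pulse_train()`, `plot_iv()`, `autoplot(sim)` (spike
raster), `plot_weights()`, `plot_rates()`.

A command-line driver is provided at `inst/cli/memwm`
(`memwm device {sweep,pulses,fit}`, `memwm run`, `memwm fixtures`), a
thin wrapper over the exported functions; the bundled configuration is
`inst/extdata/wm_experiment.yaml`.

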