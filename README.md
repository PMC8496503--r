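# memhh

Conductance-based simulation of the space-clamped **Hodgkin–Huxley (HH)**
squid-axon neuron and a **memristive variant (MHH)** in which the Na⁺ and K⁺
channel conductance scales are supplied by flux-controlled memristors. The
package is aimed at computational-neuroscience and neuromorphic-circuit work
that needs deterministic, unit-consistent, test-backed traces of membrane
potential, gate variables, branch currents and (mem)conductances under
standard stimulus and voltage-clamp protocols.

## The model

Membrane equation (space-clamped, mV / ms / µF·cm⁻² / mA·cm⁻² units):

    C dV/dt = 1000 (J_ext − J_Na − J_K − J_L),   J_x = g_x (V − E_x) / 1000

with g_Na = ḡ_Na m³h, g_K = ḡ_K n⁴, g_L = ḡ_L and first-order gate kinetics
dx/dt = α_x(1 − x) − β_x x, every rate scaled by the temperature factor
φ = 3^((T − 6.3)/10). Defaults: ḡ_Na, ḡ_K, ḡ_L = 120, 36, 0.3 mS/cm²;
E_Na, E_K, E_L = 50, −70, −50 mV; V_rest = −65 mV.

In the memristive variant the conductance scales become memductances of two
flux-controlled memristors,

    g_MNa = m³h / M(φ_Na),   g_MK = n⁴ / M(φ_K),
    M(φ)  = clip(−3.98·10⁴ φ + 10⁴, 100, 20000) Ω·cm²,
    dφ/dt = k (V − V_rest),  k = 10⁻³,

so each channel's maximal conductance evolves with the voltage history. See
`vignette("memhh-methods")` for why this continuous law (and the flux drive)
are reconstructions, what they reproduce, and what they provably cannot.

## A worked example

Repetitive firing under constant drive, at 15 °C:

```r
library(memhh)

tr <- run_current_clamp("hh", stim_constant(0.08, 20),
                        options = kinetics_options(temperature = 15))
sp <- detect_spikes(tr, method = "prominence")
sp
#> <memhh_spikes> 6 spike(s) [prominence method]
#>  peak times (ms): 0.55, 4.145, 7.35, 10.54, 13.73, 16.92
glance(sp)
#> # A tibble: 1 × 4
#>   count mean_isi mean_fwhm first_spike_latency
#>   <int>    <dbl>     <dbl>               <dbl>
#> 1     6     3.27     0.966                0.55
```

Six membrane-potential events in 20 ms with a mean interspike interval of
3.27 ms — the classic speed-up of firing with temperature (the same protocol
gives 3 events at 6.3 °C and 9 at 20 °C; `detect_spikes()` also offers the
stricter 0-mV threshold criterion, under which only the first, full-height
action potential counts — the vignette explains when each criterion is the
right one).

Voltage clamp 20 mV above rest at 6.3 °C, and the conductance peaks:

```r
cl <- run_voltage_clamp("hh", clamp_spec(20, 10))
dplyr::filter(trace_extrema(cl), series %in% c("g_K", "g_Na"))
#> # A tibble: 2 × 5
#>   series   max t_max    min t_min
#>   <chr>  <dbl> <dbl>  <dbl> <dbl>
#> 1 g_Na    2.23  1.52 0.0106     0
#> 2 g_K     4.53 10    0.367      0
```

The transient sodium conductance peaks at 2.23 mS/cm² near 1.5 ms and
inactivates; the potassium conductance rises monotonically to 4.53 mS/cm².

HH vs MHH under the single-pulse comparison protocol:

```r
pair <- run_preset("fig11")           # 0.1 mA/cm², 0.1 ms pulse, 18.5 °C
compare_models(pair$hh, pair$mhh)
#> # A tibble: 8 × 4
#>   metric           hh         mhh   delta
#> 1 spike_count   1       0          -1
#> 2 peak_V       29.7   -50.8       -80.6
#> ...
```

The HH neuron fires (peak +29.7 mV); the reconstructed memristive neuron
cannot ignite from this weak pulse because its flux state cannot cross the
memristance window in 5 ms — a documented, deliberate outcome analysed in
the vignette.

Every protocol is available as a preset (`preset_names()`), YAML experiment
configs are supported (`load_config()`, `run_config()`), traces serialise
to CSV (`write_trace()` / `read_trace()`), and `ggplot2::autoplot(tr)`
draws the standard panel figure. A thin CLI lives in `inst/scripts/memhh`
(subcommands `simulate`, `clamp`, `analyze`, `compare`, `presets`).

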