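# itfx — individual theta frequency extraction from task EEG

Frequency-personalized brain stimulation (tACS/otDCS) for associative memory
needs a per-person stimulation frequency, but unlike the alpha rhythm, theta
rarely shows a clean peak in a resting power spectrum. `itfx` implements an
extraction method that instead looks for the dominant theta frequency in the
EEG recorded *while associative memories are successfully formed*, and scores
how reliable that estimate is for each person.

## The method

EEG is recorded during a paired-associates task (42 face–scene pairs at
encoding; 84 intact/recombined pairs at recognition). Encoding epochs
(−1000…2500 ms around stimulus onset, baseline −800…0 ms) are kept when the
pair is later correctly recognized as "old" (successful encoding). Each
retained epoch is decomposed with complex Morlet wavelets (7 cycles,
1–15 Hz in 0.5 Hz steps), and event-related spectral perturbation (ERSP) is
formed as

    ERSP(c, f, t) = (1/N) Σₙ |X(c, f, t, n)|²

expressed as a ratio to the mean pre-stimulus baseline power, reported on the
2–15 Hz grid. For each of 19 overlapping time windows (100 ms wide, 50 ms
steps, 250–1250 ms) and each of six centroparietal electrodes (Cz, C3, C4,
Pz, P3, P4), the frequency with the highest ERSP is entered into a
19 × 6 = 114-cell matrix. The **individual theta frequency (ITF)** is the
mode of the matrix cells that fall in the theta band [4, 8) Hz, and its
**reliability** is the share of theta cells carrying that mode, classified
as singular (> 0.80), highly reliable (0.50–0.80], reliable (0.30–0.50],
unreliable [0.15–0.30], or none (< 0.15, below the 1-in-8 chance level).
When theta peaks are scarce (< 20% of cells), the matrix is rebuilt with
PO7/PO8 appended. An identical analysis of eyes-open resting EEG (3500 ms
pseudo-epochs, first second as baseline) serves as a control, compared by a
paired Wilcoxon signed-rank test on theta shares.

The package also ships a synthetic-EEG generator (1/f background, posterior
alpha with a waxing-and-waning envelope, event-locked theta bursts of known
frequency on centroparietal channels, and matched event/behavior tables), so
every stage of the pipeline is verifiable without real recordings.

## Worked example

```r
library(itfx)

# a synthetic session: 42 pairs, theta burst planted at 5.5 Hz, hit rate 59.5%
sim <- simulate_session(sim_params(theta_freq_hz = 5.5, seed = 42))
report <- run_extract(sim$recording, sim$events, sim$behavior)
report
#> <itf_result> ITF = 5.5 Hz (reliability 0.55, highly_reliable)
#>   band shares: delta 9.6% | theta 82.5% | alpha 3.5% | other 4.4% (114 cells, 94 theta)
report$n_epochs_used
#> [1] 25
```

The planted 5.5 Hz is recovered grid-exactly: 94 of the 114 cells peak in
theta, 55% of those at 5.5 Hz, so the estimate is classed *highly reliable* —
a tACS/otDCS protocol tuned to it would count as well-personalized. The
resting control on the same "subject":

```r
rest <- run_control(simulate_resting(sim_params(seed = 42), duration_s = 120),
                    am_report = report)
rest$band_shares["theta"]          # 43% at rest vs 82.5% during the task
rest$theta_share_task_minus_rest
```

A command-line front end with `extract`, `control`, `simulate`, and `report`
subcommands is installed under `inst/cli/itfx`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","itfx",package="itfx"))')" \
  simulate --theta 6 --seed 7 --out demo
```

File formats: EDF or a JSON fixture container for recordings
(`read_recording()`), TSV for event/behavior tables (`read_events()`,
`read_behavior()`), JSON reports and TSV peak matrices on output.

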