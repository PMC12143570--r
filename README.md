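# burstfusion

Simulation and analysis of a two-alternative **multisensory detection
task** in which a hidden target (think: prey darting between cover) emits
**bursts** of direction-informative signals against a noisy background, and
of the classifier families that solve it by fusing evidence **across
sensory channels and across time**.

## The science

Each trial hides a direction $M \in \{-1,+1\}$. Over $n$ time steps, bursts
of emission start with probability $p_g$ per step and last $L$ steps, with
$L$ fixed at $k$, uniform on $1..L_{\max}$, or heavy-tailed
($P(L=\ell) \propto 1/\ell^2$, a truncated Lévy law). While emitting, each
of $N_c$ trinary channels reports $M$ with probability $p_c$, $-M$ with
probability $p_i$, else 0; while silent, channels report symmetric noise
(0 with probability $p_n$). All-silent trials are resampled, and $p_g$ is
solved from the closed form

$$p_e = P(E_t = 1 \mid \neg F) = \frac{1-(1-p_g)^k}{1-(1-p_g)^{n+k-1}}$$

(and its general-length analogue) so every task variant carries the same
expected signal fraction $p_e$ — the information budget is constant, only
its temporal arrangement changes.

On top of the generator the package implements:

| model | features | parameters ($N_c=2$) | fuses |
|---|---|---|---|
| `lf` | per-channel value counts | 6 | channels linearly, time order-free |
| `nlf` | per-step joint patterns | 9 | channels nonlinearly, time order-free |
| `nlf2`, `nlf3` | sliding-window joint patterns | 81, 729 | channels **and** short windows |
| `rnn` | ReLU recurrence, summed outputs | ~10⁴ | channels and prior states |

plus a brute-force Bayes oracle (`exact_posterior()`) for tiny trials —
the optimal rule marginalises over $(1+L_{\max})^{n+L_{\max}-1}$ hidden
burst configurations and is intractable at realistic $n$, which is why the
window and recurrent approximations matter — and an experiment harness for
in-distribution, out-of-distribution and mixed-burst-length accuracy
grids.

## Worked example

Train a window-2 nonlinear-fusion classifier on the fixed-length task with
2-step bursts at the standard parameters, and test it on fresh trials:

```r
library(burstfusion)

cfg <- task_spec(2, n = 200)        # k = 2 bursts, p_e = 0.04
cfg
#> <task_config>
#>   n = 200 steps, 2 channel(s); burst model: fixed k=2
#>   p_c = 0.45, p_i = 0.01, p_n = 0.33
#>   sparsity p_e = 0.04 -> burst-start p_g = 0.0198407

trials <- sample_trials(cfg, 5000, seed = 1)
fit <- fit_fusion(trials, "nlf2")
fit
#> <fusion_fit> NLF2: 81 coefficients (+ intercept), 2 channel(s)
#>   trained on 5000 trials (2551 with m = +1), ridge lambda = 0.001

evaluate_accuracy(fit, sample_trials(cfg, 5000, seed = 2))
#> # A tibble: 1 × 5
#>   accuracy n_trials n_correct conf_low conf_high
#>      <dbl>    <int>     <int>    <dbl>     <dbl>
#> 1    0.696     5000      3482    0.683     0.709
```

The solved `p_g = 0.0198` is the burst-start rate at which 2-step bursts
occupy 4% of a 200-step trial on average (given at least one burst); the
classifier decodes the direction of 69.6% of held-out trials from pattern
counts alone. `tidy(fit)` exposes the 81 per-pattern weights (large-sample
log-likelihood ratios of each 2-step, 2-channel window pattern),
`autoplot(fit)` plots them, and `run_generalisation_grid()` scales this
train/test cycle over burst-length distributions.

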