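# spastimu

Machine-learning grading of **elbow spasticity** on the modified Ashworth
scale (MAS) from wearable inertial sensor recordings of passive stretch
tests.

Spasticity — a velocity-dependent increase in muscle tone — is routinely
graded by a therapist who moves the patient's relaxed elbow through
flexion–extension cycles and rates the felt resistance on the six-level MAS
(`0, 1, 1+, 2, 3, 4`). The rating is subjective; `spastimu` implements a
sensor-based pipeline that reproduces it from a forearm-mounted IMU
(triaxial accelerometer in g, triaxial gyroscope in deg/s, 256 Hz):

1. **Simulation** — a generative model of the manoeuvre (quasi-static hold,
   five 1 Hz flexion–extension cycles, grade-dependent range of motion and a
   *catch*: a transient velocity notch that deepens with severity), used to
   build labeled cohorts since no public corpus exists
   (`simulate_cohort()`).
2. **Preprocessing** — baseline holds discarded by a gyro-magnitude
   threshold, then the middle three of five cycles kept by equal division
   (`trim_baseline()`, `extract_middle_cycles()`).
3. **Segmentation** — each portion windowed without overlap (3 windows,
   dataset DS1) and with 50% overlap (5 windows, DS2).
4. **Features** — FS1: 7 statistics (rms, mean, std, energy, spectral
   energy, mean absolute successive difference, variance) × 6 channels = 42;
   FS2 adds the same statistics on roll = (180/π)·atan2(a_y, a_z) and
   pitch = (180/π)·atan2(a_x, a_z), plus the signal magnitude area
   SMA = Σ(|x_i|+|y_i|)/n and signal vector magnitude SV = Σ√(x_i²+y_i²)/n
   of the accelerometer x/y axes: 58 features.
5. **Evaluation** — decision tree, random forest, SVM, LDA and MLP under
   leave-one-subject-out cross-validation for all 2×2×5 conditions, with
   median-accuracy aggregation, per-class precision/recall, and paired
   exact Wilcoxon signed-rank comparisons of feature sets and segmentation
   schemes (`run_condition_grid()`, `wilcoxon_compare()`).

## Worked example

```r
library(spastimu)
cfg <- pipeline_config(
  cohort = c(`0` = 17, `1` = 13, `2` = 7, `3` = 6, `4` = 4, `5` = 1),
  seed = 1)
rep <- run_pipeline(cfg)
print(rep)
```

```
<pipeline_report> 48 recordings
  DS1: 144 segments (51/39/21/18/12/3)
  DS2: 240 segments (85/65/35/30/20/5)
<condition_grid> 20 conditions, leave-one-subject-out
  median accuracy by classifier:
    DT   90.8%
    LDA  96.9%
    MLP  92.1%
    RF   92.6%
    SVM  68.8%
  fs1_vs_fs2: p = 0.8125 (exact)
  ds1_vs_ds2: p = 0.1953 (exact)
```

The 48-subject cohort (17/13/7/6/4/1 across grades) yields exactly 3
non-overlapping and 5 overlapping segments per recording, hence 144 and 240
segments. Each of the 20 dataset × feature-set × classifier conditions is a
full leave-one-subject-out run; the medians above pool each classifier's
four conditions. The Wilcoxon lines compare the paired condition accuracies
(FS1 vs FS2, DS1 vs DS2) with exact two-sided p-values.

Per-class metrics for one condition:

```r
per_class_metrics(rep$grid$results[["DS2.FS2.RF"]])
```

```
  label mas_score n_true precision    recall class_accuracy
1     0         0     85 0.9655172 0.9882353      0.9768763
2     1         1     65 0.9117647 0.9538462      0.9328054
3     2        1+     35 1.0000000 0.7714286      0.8857143
4     3         2     30 0.9090909 1.0000000      0.9545455
5     4         3     20 0.8000000 1.0000000      0.9000000
6     5         4      5        NA 0.0000000             NA
```

The MAS 4 class has a single subject, so leave-one-subject-out can never
train on it: its recall is 0 and its precision undefined (`NA`), which the
package reports rather than hiding.

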