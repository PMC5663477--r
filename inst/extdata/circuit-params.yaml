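counts:
  E: 1700.0
  Ipv: 70.0
  I5ht: 115.0
  Isom: 45.0
  EL4: 1500.0
vrest:
  E: -68.0
  Ipv: -68.0
  I5ht: -62.0
  Isom: -57.0
vth:
  E: -38.0
  Ipv: -37.4
  I5ht: -36.0
  Isom: -40.0
rin:
  E: 160.0
  Ipv: 100.0
  I5ht: 200.0
  Isom: 250.0
taum:
  E: 28.0
  Ipv: 21.0
  I5ht: 10.0
  Isom: 30.0
tref:
  E: 55.5
  Ipv: 5.4
  I5ht: 21.3
  Isom: 20.0
tausyn_e:
  E: 2.0
  Ipv: 2.0
  I5ht: 2.0
  Isom: 2.0
tausyn_i:
  E: 40.0
  Ipv: 16.0
  I5ht: 40.0
  Isom: 40.0
erev_e:
  E: 0.0
  Ipv: 0.0
  I5ht: 0.0
  Isom: 0.0
erev_i:
  E: -68.0
  Ipv: -68.0
  I5ht: -62.0
  Isom: -57.0
pcon:
  EL4:
    E: 0.15
    Ipv: 0.15
    I5ht: 0.0
    Isom: 0.15
  E:
    E: 0.17
    Ipv: 0.575
    I5ht: 0.24
    Isom: 0.5
  Ipv:
    E: 0.6
    Ipv: 0.55
    I5ht: 0.24
    Isom: 0.0
  I5ht:
    E: 0.465
    Ipv: 0.38
    I5ht: 0.38
    Isom: 0.0
  Isom:
    E: 0.5
    Ipv: 0.0
    I5ht: 0.0
    Isom: 0.0
prel:
  EL4:
    E: 0.25
    Ipv: 0.25
    I5ht: 0.0
    Isom: 0.25
  E:
    E: 0.25
    Ipv: 0.25
    I5ht: 0.25
    Isom: 0.25
  Ipv:
    E: 0.25
    Ipv: 0.25
    I5ht: 0.25
    Isom: 0.0
  I5ht:
    E: 0.25
    Ipv: 0.25
    I5ht: 0.25
    Isom: 0.0
  Isom:
    E: 0.25
    Ipv: 0.0
    I5ht: 0.0
    Isom: 0.0
w_mean:
  EL4:
    E: 0.8
    Ipv: 0.8
    I5ht: 0.0
    Isom: 0.8
  E:
    E: 0.37
    Ipv: 0.82
    I5ht: 0.39
    Isom: 0.5
  Ipv:
    E: 0.52
    Ipv: 0.56
    I5ht: 0.83
    Isom: 0.0
  I5ht:
    E: 0.49
    Ipv: 0.49
    I5ht: 0.37
    Isom: 0.0
  Isom:
    E: 0.5
    Ipv: 0.0
    I5ht: 0.0
    Isom: 0.0
w_median:
  EL4:
    E: 0.48
    Ipv: 0.48
    I5ht: 0.0
    Isom: 0.48
  E:
    E: 0.2
    Ipv: 0.68
    I5ht: 0.19
    Isom: 0.4
  Ipv:
    E: 0.29
    Ipv: 0.44
    I5ht: 0.6
    Isom: 0.0
  I5ht:
    E: 0.3
    Ipv: 0.15
    I5ht: 0.23
    Isom: 0.0
  Isom:
    E: 0.4
    Ipv: 0.0
    I5ht: 0.0
    Isom: 0.0
psp_cap: 8.0
ipsp_hold: -55.0
dt: 0.01
trial_ms: 50.0
l4_center_ms: 25.0
l4_jitter_ms: 2.0
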