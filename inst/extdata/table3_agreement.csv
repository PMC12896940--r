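slide_id,n_raters,percent_agreement,fleiss_kappa
P 230117 7D 22 88 F1,3,71.9,73.7
P 230117 7D 19 72 F1,3,77.7,79.9
P 210117 7D 23 130 F1,3,76.6,78.5
P 110618 7D 31 297 F2A V2,3,83.3,85.2
P 110618 7D 30 257 F4 V2,3,87.2,88.2
P 110618 7D 30 243 F2A V2,3,76.2,79.1
P 110618 7D 29 237 F4 V2,3,87.8,89.0
P 110618 7D 28 249 F2A V2,3,73.4,76.4
P 110618 7D 28 227 F2A V2,3,69.0,71.9
P 110618 7D 27 225 F4 V2,3,85.7,86.6
P 110618 7D 27 215 F4 V2,3,81.6,83.6
P 110618 7D 27 206 F2A V2,3,79.8,82.0
P 110618 7D 28 247 F4 V2,2,NA,82.9
P 220117 7D 23 116 F1,2,NA,77.7
P 230117 7D 21 80 F1,2,NA,79.8
P 150318 7D 36 523 F4 V2,2,NA,83.0
P 150318 7D 31 287 F4 V2,2,NA,84.9
P 150318 7D 30 302 F4 V2,2,NA,82.7
P 150318 7D 30 271 F4 V2,2,NA,83.7
P 150318 7D 29 282 F2A V2,2,NA,74.5
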