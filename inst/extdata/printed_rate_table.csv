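medium,mechanism,radical,antioxidant,k_app,gamma_printed,diffusion_controlled
water,HAT,HO,PS,2.61e+09,3,TRUE
water,HAT,HO,PSE,2.63e+09,3,TRUE
water,HAT,HO,PTE,2.58e+09,3,TRUE
water,HAT,HOO,PS,1.96e+09,100,TRUE
water,HAT,HOO,PSE,1.98e+09,97,TRUE
water,HAT,HOO,PTE,1.96e+09,23,TRUE
water,HAT,CH3OO,PS,1.69e+09,100,TRUE
water,HAT,CH3OO,PSE,1.69e+09,99,TRUE
water,HAT,CH3OO,PTE,1.68e+09,32,TRUE
water,RAF,HO,PS,6.94e+10,86,TRUE
water,RAF,HO,PSE,7.24e+10,87,TRUE
water,RAF,HO,PTE,7.1e+10,87,TRUE
water,RAF,HOO,PS,16.7,0,FALSE
water,RAF,HOO,PSE,26,0,FALSE
water,RAF,HOO,PTE,15.5,0,FALSE
water,RAF,CH3OO,PS,0.372,0,FALSE
water,RAF,CH3OO,PSE,0.353,0,FALSE
water,RAF,CH3OO,PTE,0.509,0,FALSE
water,SET,HO,PS,8.53e+09,11,TRUE
water,SET,HO,PSE,8.47e+09,10,TRUE
water,SET,HO,PTE,8.43e+09,10,TRUE
water,SET,HOO,PS,3620000,0,FALSE
water,SET,HOO,PSE,70200000,3,FALSE
water,SET,HOO,PTE,6.76e+09,77,TRUE
water,SET,CH3OO,PS,385000,0,FALSE
water,SET,CH3OO,PSE,9120000,1,FALSE
water,SET,CH3OO,PTE,3.39e+09,68,TRUE
water,overall,HO,PS,8.05e+10,,TRUE
water,overall,HO,PSE,8.35e+10,,TRUE
water,overall,HO,PTE,8.21e+10,,TRUE
water,overall,HOO,PS,1.96e+09,,TRUE
water,overall,HOO,PSE,2.05e+09,,TRUE
water,overall,HOO,PTE,8.72e+09,,TRUE
water,overall,CH3OO,PS,1.69e+09,,TRUE
water,overall,CH3OO,PSE,1.7e+09,,TRUE
water,overall,CH3OO,PTE,5.07e+09,,TRUE
pentyl_ethanoate,HAT,HO,PS,2.87e+09,7,TRUE
pentyl_ethanoate,HAT,HO,PSE,2.91e+09,7,TRUE
pentyl_ethanoate,HAT,HO,PTE,2.81e+09,8,TRUE
pentyl_ethanoate,HAT,HOO,PS,5630,100,FALSE
pentyl_ethanoate,HAT,HOO,PSE,3660,100,FALSE
pentyl_ethanoate,HAT,HOO,PTE,1240,100,FALSE
pentyl_ethanoate,HAT,CH3OO,PS,1550,100,FALSE
pentyl_ethanoate,HAT,CH3OO,PSE,906,100,FALSE
pentyl_ethanoate,HAT,CH3OO,PTE,395,100,FALSE
pentyl_ethanoate,RAF,HO,PS,3.8e+10,93,TRUE
pentyl_ethanoate,RAF,HO,PSE,3.78e+10,93,TRUE
pentyl_ethanoate,RAF,HO,PTE,3.33e+10,92,TRUE
pentyl_ethanoate,RAF,HOO,PS,0.0432,0,FALSE
pentyl_ethanoate,RAF,HOO,PSE,0.0504,0,FALSE
pentyl_ethanoate,RAF,HOO,PTE,0.0447,0,FALSE
pentyl_ethanoate,RAF,CH3OO,PS,0.000186,0,FALSE
pentyl_ethanoate,RAF,CH3OO,PSE,0.000213,0,FALSE
pentyl_ethanoate,RAF,CH3OO,PTE,0.00035,0,FALSE
pentyl_ethanoate,SET,HO,PS,8.8e-19,0,FALSE
pentyl_ethanoate,SET,HO,PSE,6.84e-15,0,FALSE
pentyl_ethanoate,SET,HO,PTE,7.45e-22,0,FALSE
pentyl_ethanoate,SET,HOO,PS,2.6e-31,0,FALSE
pentyl_ethanoate,SET,HOO,PSE,2.87e-28,0,FALSE
pentyl_ethanoate,SET,HOO,PTE,9.6e-30,0,FALSE
pentyl_ethanoate,SET,CH3OO,PS,9.24e-33,0,FALSE
pentyl_ethanoate,SET,CH3OO,PSE,1.13e-29,0,FALSE
pentyl_ethanoate,SET,CH3OO,PTE,2.65e-31,0,FALSE
pentyl_ethanoate,overall,HO,PS,4.09e+10,,TRUE
pentyl_ethanoate,overall,HO,PSE,4.07e+10,,TRUE
pentyl_ethanoate,overall,HO,PTE,3.61e+10,,TRUE
pentyl_ethanoate,overall,HOO,PS,5630,,FALSE
pentyl_ethanoate,overall,HOO,PSE,3660,,FALSE
pentyl_ethanoate,overall,HOO,PTE,1240,,FALSE
pentyl_ethanoate,overall,CH3OO,PS,1550,,FALSE
pentyl_ethanoate,overall,CH3OO,PSE,906,,FALSE
pentyl_ethanoate,overall,CH3OO,PTE,395,,FALSE
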