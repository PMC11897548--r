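HETATM    1  MG  BCL A   1      28.743  11.613  16.500  1.00  0.00          MG
HETATM    2  NB  BCL A   1      29.960  10.818  16.870  1.00  0.00          NB
HETATM    3  ND  BCL A   1      27.526  12.408  16.130  1.00  0.00          ND
HETATM    4  MG  BCL B   2      14.554  27.371  16.500  1.00  0.00          MG
HETATM    5  NB  BCL B   2      15.997  27.545  16.870  1.00  0.00          NB
HETATM    6  ND  BCL B   2      13.110  27.198  16.130  1.00  0.00          ND
HETATM    7  MG  BCL C   3      -6.445  30.323  16.500  1.00  0.00          MG
HETATM    8  NB  BCL C   3      -5.451  31.383  16.870  1.00  0.00          NB
HETATM    9  ND  BCL C   3      -7.439  29.262  16.130  1.00  0.00          ND
HETATM   10  MG  BCL D   4     -24.428  19.086  16.500  1.00  0.00          MG
HETATM   11  NB  BCL D   4     -24.348  20.537  16.870  1.00  0.00          NB
HETATM   12  ND  BCL D   4     -24.508  17.634  16.130  1.00  0.00          ND
HETATM   13  MG  BCL E   5     -30.981  -1.082  16.500  1.00  0.00          MG
HETATM   14  NB  BCL E   5     -31.853   0.081  16.870  1.00  0.00          NB
HETATM   15  ND  BCL E   5     -30.109  -2.245  16.130  1.00  0.00          ND
HETATM   16  MG  BCL F   6     -23.037 -20.743  16.500  1.00  0.00          MG
HETATM   17  NB  BCL F   6     -24.453 -20.412  16.870  1.00  0.00          NB
HETATM   18  ND  BCL F   6     -21.622 -21.074  16.130  1.00  0.00          ND
HETATM   19  MG  BCL G   7      -4.314 -30.698  16.500  1.00  0.00          MG
HETATM   20  NB  BCL G   7      -5.611 -31.355  16.870  1.00  0.00          NB
HETATM   21  ND  BCL G   7      -3.017 -30.042  16.130  1.00  0.00          ND
HETATM   22  MG  BCL H   8      16.427 -26.289  16.500  1.00  0.00          MG
HETATM   23  NB  BCL H   8      15.856 -27.626  16.870  1.00  0.00          NB
HETATM   24  ND  BCL H   8      16.999 -24.953  16.130  1.00  0.00          ND
HETATM   25  MG  BCL I   9      29.483  -9.580  16.500  1.00  0.00          MG
HETATM   26  NB  BCL I   9      29.904 -10.971  16.870  1.00  0.00          NB
HETATM   27  ND  BCL I   9      29.062  -8.188  16.130  1.00  0.00          ND
HETATM   28  MG  BCL A  10      22.986  -4.886   0.000  1.00  0.00          MG
HETATM   29  NB  BCL A  10      21.792  -5.774  -0.183  1.00  0.00          NB
HETATM   30  ND  BCL A  10      24.181  -3.998   0.183  1.00  0.00          ND
HETATM   31  MG  BCL A  11      22.986   4.886   0.000  1.00  0.00          MG
HETATM   32  NB  BCL A  11      23.764   6.156   0.183  1.00  0.00          NB
HETATM   33  ND  BCL A  11      22.209   3.616  -0.183  1.00  0.00          ND
HETATM   34  MG  BCL B  12      20.749  11.033   0.000  1.00  0.00          MG
HETATM   35  NB  BCL B  12      20.405   9.584  -0.183  1.00  0.00          NB
HETATM   36  ND  BCL B  12      21.094  12.481   0.183  1.00  0.00          ND
HETATM   37  MG  BCL B  13      14.468  18.518   0.000  1.00  0.00          MG
HETATM   38  NB  BCL B  13      14.247  19.991   0.183  1.00  0.00          NB
HETATM   39  ND  BCL B  13      14.689  17.046  -0.183  1.00  0.00          ND
HETATM   40  MG  BCL C  14       8.803  21.789   0.000  1.00  0.00          MG
HETATM   41  NB  BCL C  14       9.471  20.458  -0.183  1.00  0.00          NB
HETATM   42  ND  BCL C  14       8.136  23.120   0.183  1.00  0.00          ND
HETATM   43  MG  BCL C  15      -0.820  23.486   0.000  1.00  0.00          MG
HETATM   44  NB  BCL C  15      -1.936  24.472   0.183  1.00  0.00          NB
HETATM   45  ND  BCL C  15       0.296  22.500  -0.183  1.00  0.00          ND
HETATM   46  MG  BCL D  16      -7.262  22.350   0.000  1.00  0.00          MG
HETATM   47  NB  BCL D  16      -5.895  21.759  -0.183  1.00  0.00          NB
HETATM   48  ND  BCL D  16      -8.629  22.940   0.183  1.00  0.00          ND
HETATM   49  MG  BCL D  17     -15.725  17.464   0.000  1.00  0.00          MG
HETATM   50  NB  BCL D  17     -17.213  17.502   0.183  1.00  0.00          NB
HETATM   51  ND  BCL D  17     -14.236  17.426  -0.183  1.00  0.00          ND
HETATM   52  MG  BCL E  18     -19.929  12.453   0.000  1.00  0.00          MG
HETATM   53  NB  BCL E  18     -18.503  12.879  -0.183  1.00  0.00          NB
HETATM   54  ND  BCL E  18     -21.356  12.027   0.183  1.00  0.00          ND
HETATM   55  MG  BCL E  19     -23.271   3.271   0.000  1.00  0.00          MG
HETATM   56  NB  BCL E  19     -24.436   2.343   0.183  1.00  0.00          NB
HETATM   57  ND  BCL E  19     -22.107   4.198  -0.183  1.00  0.00          ND
HETATM   58  MG  BCL F  20     -23.271  -3.271   0.000  1.00  0.00          MG
HETATM   59  NB  BCL F  20     -22.452  -2.027  -0.183  1.00  0.00          NB
HETATM   60  ND  BCL F  20     -24.090  -4.514   0.183  1.00  0.00          ND
HETATM   61  MG  BCL F  21     -19.929 -12.453   0.000  1.00  0.00          MG
HETATM   62  NB  BCL F  21     -20.225 -13.912   0.183  1.00  0.00          NB
HETATM   63  ND  BCL F  21     -19.633 -10.994  -0.183  1.00  0.00          ND
HETATM   64  MG  BCL G  22     -15.725 -17.464   0.000  1.00  0.00          MG
HETATM   65  NB  BCL G  22     -15.896 -15.985  -0.183  1.00  0.00          NB
HETATM   66  ND  BCL G  22     -15.553 -18.943   0.183  1.00  0.00          ND
HETATM   67  MG  BCL G  23      -7.262 -22.350   0.000  1.00  0.00          MG
HETATM   68  NB  BCL G  23      -6.551 -23.658   0.183  1.00  0.00          NB
HETATM   69  ND  BCL G  23      -7.973 -21.042  -0.183  1.00  0.00          ND
HETATM   70  MG  BCL H  24      -0.820 -23.486   0.000  1.00  0.00          MG
HETATM   71  NB  BCL H  24      -1.902 -22.463  -0.183  1.00  0.00          NB
HETATM   72  ND  BCL H  24       0.262 -24.508   0.183  1.00  0.00          ND
HETATM   73  MG  BCL H  25       8.803 -21.789   0.000  1.00  0.00          MG
HETATM   74  NB  BCL H  25      10.189 -22.334   0.183  1.00  0.00          NB
HETATM   75  ND  BCL H  25       7.418 -21.244  -0.183  1.00  0.00          ND
HETATM   76  MG  BCL I  26      14.468 -18.518   0.000  1.00  0.00          MG
HETATM   77  NB  BCL I  26      12.982 -18.431  -0.183  1.00  0.00          NB
HETATM   78  ND  BCL I  26      15.954 -18.606   0.183  1.00  0.00          ND
HETATM   79  MG  BCL I  27      20.749 -11.033   0.000  1.00  0.00          MG
HETATM   80  NB  BCL I  27      22.161 -10.559   0.183  1.00  0.00          NB
HETATM   81  ND  BCL I  27      19.338 -11.506  -0.183  1.00  0.00          ND
END
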