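rank,CAR,PXR,AR,PPARa,PPARg,PPARd,RORgt
1,446255-01-2,446255-18-1,147217-74-1,405237-85-6,446254-32-6,366791-32-4,446255-08-9
2,446254-72-4,446254-80-4,446254-24-6,446254-95-1,68631-49-2,373594-78-6,373594-78-6
3,218304-36-0,93703-48-1,337513-55-0,51452-87-0,337513-67-4,446254-48-4,366791-32-4
4,446254-55-3,446254-86-0,337513-68-5,446254-71-3,171977-44-9,405237-85-6,446254-82-6
5,446254-63-3,373594-78-6,446254-62-2,83694-71-7,446254-80-4,337513-68-5,446254-31-5
6,117948-63-7,366791-32-4,446254-45-1,147217-72-9,189084-59-1,446254-82-6,446255-18-1
7,446254-33-7,446255-07-8,446254-28-0,446254-70-2,46438-88-4,103173-66-6,446254-27-9
8,446254-17-7,446254-45-1,147217-76-3,446255-17-0,60348-60-9,446254-77-9,446254-70-2
9,446254-30-4,446254-28-0,446254-19-9,446254-97-3,147217-77-4,446254-84-8,446254-71-3
10,327185-09-1,189084-61-5,446254-15-5,366791-32-4,337513-54-9,446254-32-6,182677-28-7
11,446254-21-3,446254-29-1,49690-94-0,446254-27-9,446254-65-5,446254-39-3,446254-48-4
12,446254-32-6,446254-31-5,189084-62-6,446254-38-2,5436-43-1,446254-31-5,405237-85-6
13,446254-35-9,446254-39-3,147217-75-2,446254-48-4,189084-61-5,446254-64-4,446254-80-4
14,446254-36-0,446254-82-6,407606-55-7,407606-55-7,337513-55-0,446254-18-8,93703-48-1
15,446254-37-1,446254-64-4,337513-75-4,147217-73-0,101-55-3,189084-59-1,446254-28-0
16,446254-68-8,446254-50-8,446254-30-4,446255-10-3,93703-48-1,147217-77-4,446254-81-5
17,446254-95-1,446255-13-6,337513-53-8,446255-18-1,337513-72-1,446255-13-6,327185-11-5
18,446255-00-1,446254-19-9,446254-25-7,446254-45-1,446254-70-2,446254-20-2,446254-38-2
19,446255-12-5,147217-81-0,337513-56-1,446254-39-3,366791-32-4,446254-51-9,446254-83-7
20,446255-20-5,446254-27-9,446254-18-8,446254-50-8,407606-55-7,327185-11-5,446254-34-8
21,337513-66-3,446254-38-2,337513-82-3,446254-53-1,446254-39-3,60348-60-9,446254-78-0
22,51930-04-02,446254-71-3,147217-81-0,446254-32-6,259087-35-9,446254-38-2,446255-09-0
23,189084-60-4,446254-42-8,446255-04-5,147217-71-8,417727-71-0,446255-18-1,446254-96-2
24,337513-68-5,446254-48-4,446254-27-9,101-55-3,147217-75-2,147217-76-3,147217-76-3
25,446254-22-4,446255-08-9,446254-53-1,446254-84-8,337513-66-3,446254-86-0,147217-79-6
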